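# File I/O: XYZ / GRO coordinate files, S(q) curve CSVs, JSON fit records.
# Lengths are Angstrom and q inverse Angstrom at every public boundary; GRO
# nanometre coordinates are converted on read/write.

#' Read and write particle configurations (XYZ and GRO dialects)
#'
#' The XYZ dialect is: line 1 the particle count; line 2 a comment carrying
#' the box as `box = Lx Ly Lz` (Angstrom) and optionally `T = <K>`; then one
#' `species x y z` line per particle. GRO files follow the fixed-width
#' GROMACS format with coordinates and box in nanometre (converted to
#' Angstrom on read). Files without box information are rejected.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"xyz"` or `"gro"`
#' @return a [particle_config()]
#' @export
read_configuration_file <- function(path, format = c("auto", "xyz", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_aq(paste0("file not found: ", path), "io")
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "xyz"
  }
  if (format == "xyz") read_xyz(path) else read_gro(path)
}

#' @rdname read_configuration_file
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_aq("malformed XYZ: fewer than 3 lines", "parse")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop_aq("malformed XYZ line 1: expected particle count", "parse")
  m <- regmatches(lines[2],
                  regexec("box\\s*=?\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)",
                          lines[2]))[[1]]
  if (length(m) != 4L) {
    stop_aq("XYZ comment line must carry the box as 'box = Lx Ly Lz'",
            "box_required")
  }
  box <- as.numeric(m[2:4])
  tm <- regmatches(lines[2], regexec("T\\s*=\\s*([0-9.eE+-]+)", lines[2]))[[1]]
  temperature <- if (length(tm) == 2L) as.numeric(tm[2]) else NA_real_
  body <- lines[3:(2 + n)]
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 4L)
  if (length(bad) > 0) {
    stop_aq(sprintf("malformed XYZ atom line %d", bad[1] + 2L), "parse")
  }
  species <- vapply(fields, `[[`, character(1), 1L)
  pos <- t(vapply(fields, function(f) suppressWarnings(as.numeric(f[2:4])),
                  numeric(3)))
  if (any(!is.finite(pos))) {
    bad_line <- which(rowSums(!is.finite(pos)) > 0)[1] + 2L
    stop_aq(sprintf("non-numeric coordinates on XYZ line %d", bad_line), "parse")
  }
  particle_config(pos, box = box, species = species, temperature = temperature)
}

#' @rdname read_configuration_file
#' @param config a [particle_config()]
#' @export
write_xyz <- function(config, path) {
  box <- config_box(config)
  tt <- config_temperature(config)
  comment <- sprintf("box = %.6f %.6f %.6f", box[1], box[2], box[3])
  if (length(tt) == 1 && is.finite(tt)) comment <- sprintf("%s T = %.3f", comment, tt)
  lines <- c(as.character(nrow(config)), comment,
             sprintf("%s %.6f %.6f %.6f", config$species, config$x, config$y, config$z))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_configuration_file
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_aq("malformed GRO: fewer than 3 lines", "parse")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop_aq("malformed GRO line 2: expected atom count", "parse")
  if (length(lines) < 3L + n) stop_aq("GRO truncated before box line", "box_required")
  body <- lines[3:(2 + n)]
  species <- trimws(substr(body, 11, 15))
  pos <- cbind(as.numeric(substr(body, 21, 28)),
               as.numeric(substr(body, 29, 36)),
               as.numeric(substr(body, 37, 44)))
  if (any(!is.finite(pos))) stop_aq("non-numeric coordinates in GRO body", "parse")
  boxfields <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  if (length(boxfields) < 3L || any(!is.finite(boxfields[1:3]))) {
    stop_aq("GRO box line missing or malformed", "box_required")
  }
  tm <- regmatches(lines[1], regexec("T\\s*=\\s*([0-9.eE+-]+)", lines[1]))[[1]]
  temperature <- if (length(tm) == 2L) as.numeric(tm[2]) else NA_real_
  # element label: leading letters of the atom name
  elem <- sub("^([A-Za-z]+).*$", "\\1", species)
  elem <- ifelse(grepl("^H", elem), "H", substr(elem, 1, 1))
  particle_config(pos * 10, box = boxfields[1:3] * 10, species = elem,
                  temperature = temperature)
}

#' @rdname read_configuration_file
#' @export
write_gro <- function(config, path) {
  box <- config_box(config)
  tt <- config_temperature(config)
  title <- if (length(tt) == 1 && is.finite(tt))
    sprintf("generated by aquafluct T = %.3f", tt) else "generated by aquafluct"
  n <- nrow(config)
  atoms <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   seq_len(n) %% 100000L, "MOL", substr(config$species, 1, 5),
                   seq_len(n) %% 100000L,
                   config$x / 10, config$y / 10, config$z / 10)
  lines <- c(title, sprintf("%5d", n), atoms,
             sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write structure-factor curves as CSV
#'
#' CSV with a header row and columns `q`, `S` and optionally `stderr`; `q`
#' must be strictly increasing. An optional `temperature` column (constant)
#' is stored as an attribute.
#'
#' @param path file path
#' @return tibble with columns `q`, `S` (and `stderr` when present)
#' @export
read_sq_curve <- function(path) {
  if (!file.exists(path)) stop_aq(paste0("file not found: ", path), "io")
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("q", "S") %in% names(d))) {
    stop_aq("curve CSV must have columns q and S", "parse")
  }
  if (nrow(d) == 0) stop_aq("curve file has a header but no data rows", "empty_curve")
  if (any(diff(d$q) <= 0)) {
    stop_aq("q must be strictly increasing; sort the file by q first", "parse")
  }
  temperature <- if ("temperature" %in% names(d)) d$temperature[1] else NA_real_
  out <- d[, intersect(c("q", "S", "stderr"), names(d))]
  structure(as_tibble(out), temperature = temperature, class = class(out))
}

#' @rdname read_sq_curve
#' @param curve tibble with columns `q`, `S` (optionally `stderr`)
#' @export
write_sq_curve <- function(curve, path) {
  out <- curve[, intersect(c("q", "S", "stderr"), names(curve)), drop = FALSE]
  tt <- attr(curve, "temperature")
  if (length(tt) == 1 && is.finite(tt)) out$temperature <- tt
  readr::write_csv(out, path)
  invisible(path)
}

#' JSON round trip of a SAXS decomposition record
#'
#' @param fit a `saxs_fit`
#' @param path file path
#' @return `write_saxs_json()`: the path, invisibly. `read_saxs_json()`: a
#'   `saxs_fit` object with the stored fields.
#' @export
write_saxs_json <- function(fit, path) {
  stopifnot(inherits(fit, "saxs_fit"))
  rec <- unclass(fit)
  rec$stderr <- as.list(fit$stderr)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_saxs_json
#' @export
read_saxs_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$stderr <- unlist(rec$stderr)
  rec$fit_window <- as.numeric(rec$fit_window)
  rec$temperature <- if (is.null(rec$temperature)) NA_real_ else as.numeric(rec$temperature)
  structure(rec, class = "saxs_fit")
}
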