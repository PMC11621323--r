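# Knudsen evaporative cooling of a binary (water + non-volatile solute)
# microdroplet in vacuum: free-molecular mass flux coupled to a lumped
# energy balance. Radiative and residual-gas heat exchange are neglected
# (chamber pressures of order 1 Pa).

# Saturation vapor pressure of (supercooled) liquid water, Pa.
# Murphy & Koop (2005) correlation, valid 123 < T < 332 K; the exported
# functions restrict to 150-320 K.
vapor_pressure_water <- function(T) {
  exp(54.842763 - 6763.22 / T - 4.210 * log(T) + 0.000367 * T +
        tanh(0.0415 * (T - 218.8)) *
        (53.878 - 1331.22 / T - 9.44523 * log(T) + 0.014025 * T))
}

# Latent heat of vaporization of water, J/kg (Murphy & Koop 2005, J/mol form)
latent_heat_water <- function(T) {
  (56579 - 42.212 * T + exp(0.1149 * (281.6 - T))) / (.M_WATER * 1e-3)
}

# Liquid heat capacities, J/(mol K). Water: empirical form reproducing the
# rise of c_p on supercooling (75.3 at 298 K, ~93 at 229 K); glycerol:
# constant. Mixture: ideal (mole-fraction) mixing.
cp_water_mol <- function(T) 75.3 + 0.0016 * pmax(298 - T, 0)^2.2
cp_glycerol_mol <- function(T) rep(218.9, length(T))

cp_mixture_mass <- function(T, chi_g) {
  cp_mol <- (1 - chi_g) * cp_water_mol(T) + chi_g * cp_glycerol_mol(T)
  M_bar <- ((1 - chi_g) * .M_WATER + chi_g * .M_GLYCEROL) * 1e-3 # kg/mol
  cp_mol / M_bar
}

# Liquid densities, kg/m^3; mixture via mass-fraction ideal mixing of volumes
.RHO_WATER <- 999.8
.RHO_GLYCEROL <- 1261
density_mixture <- function(chi_g) {
  w_g <- mole_to_weight_fraction(chi_g)
  1 / (w_g / .RHO_GLYCEROL + (1 - w_g) / .RHO_WATER)
}

#' Knudsen (free-molecular) evaporative mass flux
#'
#' Kinetic-theory effusion flux of water from the droplet surface into
#' vacuum, `J = alpha p_vap(T) a_w sqrt(M_w / (2 pi R T))` in kg m^-2 s^-1,
#' with the water activity from Raoult's law (`a_w = 1 - chi_g`) and the
#' saturation vapor pressure of supercooled water from the Murphy-Koop
#' correlation. The evaporation coefficient `alpha` defaults to 1 (the
#' Knudsen-limit assumption).
#'
#' @param T droplet temperature, K; must lie in 150-320 K (correlation
#'   validity range)
#' @param chi_g glycerol mole fraction
#' @param alpha evaporation coefficient in `[0, 1]`
#' @return mass flux, kg m^-2 s^-1
#' @export
knudsen_flux <- function(T, chi_g = 0, alpha = 1) {
  if (any(T < 150) || any(T > 320)) {
    stop_aq("T outside the 150-320 K validity range of the vapor-pressure correlation",
            "domain")
  }
  check_fraction(chi_g, "chi_g")
  a_w <- 1 - chi_g
  alpha * vapor_pressure_water(T) * a_w *
    sqrt(.M_WATER * 1e-3 / (2 * pi * .R_gas * T))
}

#' Initial state of an evaporating microdroplet
#'
#' @param diameter_um droplet diameter, micrometre
#' @param chi_g glycerol mole fraction
#' @param temperature initial temperature, K
#' @return one-row tibble: `time` (s), `radius_um`, `temperature` (K),
#'   `chi_g`, `mass_kg`
#' @export
droplet_state <- function(diameter_um, chi_g = 0.032, temperature = 293.15) {
  check_positive(diameter_um, "diameter_um")
  check_fraction(chi_g, "chi_g")
  check_positive(temperature, "temperature")
  r <- diameter_um * 1e-6 / 2
  mass <- (4 / 3) * pi * r^3 * density_mixture(chi_g)
  tibble(time = 0, radius_um = diameter_um / 2, temperature = temperature,
         chi_g = chi_g, mass_kg = mass)
}

#' Integrate the evaporative-cooling trajectory of a microdroplet
#'
#' Coupled mass and energy balance integrated with a fixed-step classical
#' 4th-order Runge-Kutta scheme:
#' `dm_w/dt = -4 pi r^2 J` and `dT/dt = -J L(T) 4 pi r^2 / (m c_p(T, chi_g))`,
#' with the glycerol mass conserved (non-volatile solute), `chi_g` updated
#' from the water mass loss, uniform internal temperature (lumped
#' capacitance), and the droplet radius recomputed from the total mass and
#' mixture density each step.
#'
#' @param initial one-row tibble from [droplet_state()]
#' @param duration integration time, s
#' @param step fixed time step, s
#' @param alpha evaporation coefficient (0 disables evaporation)
#' @return a `cooling_trajectory` tibble: `time` (s), `radius_um`,
#'   `temperature` (K), `chi_g`, `mass_kg`, `flux` (kg m^-2 s^-1)
#' @export
integrate_cooling <- function(initial, duration, step = 1e-6, alpha = 1) {
  check_positive(duration, "duration")
  check_positive(step, "step")
  st <- initial[nrow(initial), ]
  chi0 <- st$chi_g
  m_tot <- st$mass_kg
  M_bar <- ((1 - chi0) * .M_WATER + chi0 * .M_GLYCEROL) * 1e-3
  n_tot <- m_tot / M_bar                 # total moles
  m_g <- n_tot * chi0 * .M_GLYCEROL * 1e-3 # glycerol mass, conserved
  m_w <- m_tot - m_g
  Temp <- st$temperature

  chi_of <- function(mw) {
    n_w <- mw / (.M_WATER * 1e-3)
    n_g <- m_g / (.M_GLYCEROL * 1e-3)
    n_g / (n_w + n_g)
  }
  radius_of <- function(mw) {
    chi <- chi_of(mw)
    (3 * (mw + m_g) / (4 * pi * density_mixture(chi)))^(1 / 3)
  }
  deriv <- function(mw, Tt) {
    chi <- chi_of(mw)
    r <- radius_of(mw)
    J <- knudsen_flux(Tt, chi, alpha)
    A <- 4 * pi * r^2
    dm <- -A * J
    dT <- -J * latent_heat_water(Tt) * A / ((mw + m_g) * cp_mixture_mass(Tt, chi))
    c(dm, dT)
  }

  n_steps <- ceiling(duration / step)
  out_t <- numeric(n_steps + 1)
  out_m <- numeric(n_steps + 1)
  out_T <- numeric(n_steps + 1)
  out_J <- numeric(n_steps + 1)
  out_t[1] <- st$time
  out_m[1] <- m_w
  out_T[1] <- Temp
  out_J[1] <- knudsen_flux(Temp, chi0, alpha)
  last_valid <- 1L
  for (i in seq_len(n_steps)) {
    h <- step
    k1 <- deriv(m_w, Temp)
    k2 <- deriv(m_w + h / 2 * k1[1], Temp + h / 2 * k1[2])
    k3 <- deriv(m_w + h / 2 * k2[1], Temp + h / 2 * k2[2])
    k4 <- deriv(m_w + h * k3[1], Temp + h * k3[2])
    m_new <- m_w + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    T_new <- Temp + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    if (!is.finite(m_new) || !is.finite(T_new) || m_new <= 0 || T_new <= 0) {
      stop_aq("integration reached a nonphysical state (T <= 0 or m <= 0)",
              "integration_abort",
              last_state = tibble(time = out_t[last_valid],
                                  temperature = out_T[last_valid],
                                  mass_w = out_m[last_valid]))
    }
    if (T_new < 150) break # below the flux correlation range: stop cleanly
    m_w <- m_new
    Temp <- T_new
    out_t[i + 1] <- out_t[1] + i * h
    out_m[i + 1] <- m_w
    out_T[i + 1] <- Temp
    out_J[i + 1] <- knudsen_flux(Temp, chi_of(m_w), alpha)
    last_valid <- i + 1L
  }
  n <- last_valid
  mw <- out_m[seq_len(n)]
  chi <- vapply(mw, chi_of, numeric(1))
  traj <- tibble(
    time = out_t[seq_len(n)],
    radius_um = vapply(mw, radius_of, numeric(1)) * 1e6,
    temperature = out_T[seq_len(n)],
    chi_g = chi,
    mass_kg = mw + m_g,
    flux = out_J[seq_len(n)])
  structure(traj, step = step, alpha = alpha,
            class = c("cooling_trajectory", class(traj)))
}

#' Droplet temperature at a given flight distance
#'
#' Maps flight distance to time through a constant jet speed and linearly
#' interpolates the trajectory temperature.
#'
#' @param trajectory a `cooling_trajectory` from [integrate_cooling()]
#' @param jet_speed droplet train speed, m/s
#' @param distance_mm flight distance from the dispenser tip, mm
#' @return temperature, K
#' @export
temperature_at_distance <- function(trajectory, jet_speed, distance_mm) {
  check_positive(jet_speed, "jet_speed")
  if (any(distance_mm < 0)) stop_aq("distance must be >= 0", "out_of_range")
  t <- distance_mm * 1e-3 / jet_speed
  if (any(t > max(trajectory$time))) {
    stop_aq("distance maps beyond the integrated trajectory", "out_of_range")
  }
  approx(trajectory$time, trajectory$temperature, xout = t)$y
}
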