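# Closed-vial CH4 accounting: ideal-gas headspace mass, Henry's-law
# dissolved CH4, pore-water concentration, oxidation-rate regression, and
# gravimetric water / soil organic matter.

#' Physical constants for gas calculations
#'
#' @param R Ideal gas constant, L atm mol-1 K-1.
#' @param henry_kh Henry solubility constant of CH4 in water, mol L-1 atm-1
#'   (default 1.4e-3, a standard compilation value at 21 degrees C).
#' @param m_ch4 Molar mass of CH4, g/mol.
#' @return A `gas_constants` list.
#' @export
gas_constants <- function(R = 0.082057, henry_kh = 1.4e-3, m_ch4 = 16.04) {
  stopifnot(R > 0, henry_kh >= 0, m_ch4 > 0)
  structure(list(R = R, henry_kh = henry_kh, m_ch4 = m_ch4),
            class = "gas_constants")
}

#' Closed-bottle microcosm geometry
#'
#' Describes a serum-bottle soil incubation: the headspace volume is the
#' bottle volume minus the volume displaced by the wet soil plus the added
#' air and injected CH4. Defaults mirror a 175-mL bottle holding ~15 g peat
#' with 34 mL added air and 1 mL pure CH4, incubated at 8 degrees C.
#'
#' @param bottle_volume Bottle volume, mL.
#' @param soil_wet_mass Wet soil mass, g.
#' @param soil_density Wet soil bulk density, g/mL (default 1).
#' @param water_content Gravimetric water content of the soil, weight
#'   fraction in \[0, 1).
#' @param added_air Air added for overpressure, mL.
#' @param injected_ch4 Pure CH4 injected, mL.
#' @param incubation_temp Incubation temperature, degrees C.
#' @param pressure Headspace pressure, atm (default 1).
#' @return A `microcosm_spec` list with derived `headspace_volume` (mL) and
#'   `dry_mass` (g).
#' @export
microcosm_spec <- function(bottle_volume = 175, soil_wet_mass = 15,
                           soil_density = 1, water_content = 0.9,
                           added_air = 34, injected_ch4 = 1,
                           incubation_temp = 8, pressure = 1) {
  stopifnot(water_content >= 0, water_content < 1, soil_density > 0)
  headspace <- bottle_volume - soil_wet_mass / soil_density +
    added_air + injected_ch4
  if (headspace <= 0) abort("non-positive headspace volume")
  dry_mass <- soil_wet_mass * (1 - water_content)
  structure(list(
    bottle_volume = bottle_volume, soil_wet_mass = soil_wet_mass,
    soil_density = soil_density, water_content = water_content,
    added_air = added_air, injected_ch4 = injected_ch4,
    incubation_temp = incubation_temp, pressure = pressure,
    headspace_volume = headspace, dry_mass = dry_mass
  ), class = "microcosm_spec")
}

#' @rdname microcosm_spec
#' @param spec A `microcosm_spec`.
#' @return `dosing_fraction()` returns the headspace CH4 volume fraction
#'   obtained by the injection (injected CH4 over total headspace gas).
#' @export
dosing_fraction <- function(spec) {
  spec$injected_ch4 / spec$headspace_volume
}

#' Pore-water equilibration vial geometry
#'
#' @param vial_volume Vial volume, mL (default 20).
#' @param water_volume Pore-water volume injected, mL (default 5).
#' @param temp Equilibration temperature, degrees C (default 21).
#' @param pressure Vial pressure, atm (default 1).
#' @return A `vial_spec` list.
#' @export
vial_spec <- function(vial_volume = 20, water_volume = 5, temp = 21,
                      pressure = 1) {
  stopifnot(water_volume > 0, water_volume < vial_volume, pressure > 0)
  structure(list(vial_volume = vial_volume, water_volume = water_volume,
                 temp = temp, pressure = pressure), class = "vial_spec")
}

#' Headspace CH4 mass by the ideal gas law
#'
#' `n = fraction * pressure * volume / (R * temp)`, reported as micrograms of
#' CH4. Linear in fraction, volume and pressure.
#'
#' @param fraction CH4 volume fraction of the headspace, in \[0, 1\].
#' @param volume Headspace volume, L.
#' @param temp Temperature, K.
#' @param pressure Pressure, atm.
#' @param constants A [gas_constants()] object.
#' @return Mass of CH4 in micrograms (vectorized over `fraction`).
#' @export
#' @examples
#' headspace_ch4_mass(0.0051, 0.195, 294.15, 1)
headspace_ch4_mass <- function(fraction, volume, temp, pressure = 1,
                               constants = gas_constants()) {
  stopifnot(all(fraction >= 0), all(fraction <= 1), volume > 0, temp > 0,
            pressure > 0)
  mol <- fraction * pressure * volume / (constants$R * temp)
  mol * constants$m_ch4 * 1e6
}

#' Pore-water CH4 concentration from an equilibrated vial
#'
#' Total CH4 in the vial is the headspace amount (ideal gas law) plus the
#' dissolved amount (Henry's law at the vial temperature); because the vial
#' was flushed with N2 before injection, all of it originates from the
#' injected pore water, so the concentration is the total divided by the
#' injected pore-water volume. Monotone increasing in the Henry constant
#' and in the headspace fraction; at `henry_kh = 0` it reduces to the
#' ideal-gas-only estimate.
#'
#' @param vial A [vial_spec()].
#' @param headspace_fraction Measured CH4 volume fraction of the vial
#'   headspace.
#' @param constants A [gas_constants()] object.
#' @return CH4 concentration of the original pore water, mol/L (vectorized
#'   over `headspace_fraction`).
#' @export
porewater_ch4_concentration <- function(vial, headspace_fraction,
                                        constants = gas_constants()) {
  stopifnot(inherits(vial, "vial_spec"), all(headspace_fraction >= 0))
  temp_k <- vial$temp + 273.15
  v_head <- (vial$vial_volume - vial$water_volume) / 1000
  v_water <- vial$water_volume / 1000
  p_ch4 <- headspace_fraction * vial$pressure
  mol_gas <- p_ch4 * v_head / (constants$R * temp_k)
  mol_dissolved <- p_ch4 * constants$henry_kh * v_water
  (mol_gas + mol_dissolved) / v_water
}

#' Potential CH4 oxidation rate from a closed-vial time series
#'
#' Converts each headspace measurement to micrograms of CH4 via the ideal
#' gas law at the incubation temperature, fits an ordinary least-squares
#' line of mass against time, and reports the consumption rate as
#' `-slope * 24 / dry_mass` in ug CH4 per g dry soil per day (consumption
#' positive). A constant series yields slope 0 with an undefined R-squared
#' (reported as NA).
#'
#' @param series Tibble with column `time_h` and either `ch4_fraction`
#'   (headspace volume fraction) or `mass_ug` (micrograms CH4) per
#'   timepoint; at least two timepoints.
#' @param spec A [microcosm_spec()].
#' @param constants A [gas_constants()] object.
#' @return A `peatmob_oxidation` object with fields `rate` (ug g-1 d-1),
#'   `slope` (ug/h), `r_squared`, `dry_mass`, `fit` and `data`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
oxidation_rate <- function(series, spec = microcosm_spec(),
                           constants = gas_constants()) {
  stopifnot(inherits(spec, "microcosm_spec"), nrow(series) >= 2)
  if (is.unsorted(series$time_h, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  if (spec$dry_mass <= 0) abort("dry soil mass must be positive")
  mass <- if ("mass_ug" %in% names(series)) {
    series$mass_ug
  } else {
    headspace_ch4_mass(
      series$ch4_fraction, spec$headspace_volume / 1000,
      spec$incubation_temp + 273.15, spec$pressure, constants
    )
  }
  dat <- tibble(time_h = series$time_h, mass_ug = mass)
  fit <- lm(mass_ug ~ time_h, data = dat)
  slope <- unname(stats::coef(fit)[2])
  # exact linear series trip lm's "perfect fit" warning; that is expected here
  r2 <- if (stats::var(mass) == 0) NA_real_ else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(
    rate = -slope * 24 / spec$dry_mass,
    slope = slope,
    r_squared = r2,
    dry_mass = spec$dry_mass,
    fit = fit,
    data = dat
  ), class = "peatmob_oxidation")
}

#' @export
print.peatmob_oxidation <- function(x, ...) {
  cat(sprintf("CH4 oxidation: %.3f ug g-1 dry soil d-1 (slope %.4f ug/h, R2 %s, %d timepoints)\n",
              x$rate, x$slope,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              nrow(x$data)))
  invisible(x)
}

#' @rdname oxidation_rate
#' @param x A `peatmob_oxidation` object.
#' @param ... Unused.
#' @export
tidy.peatmob_oxidation <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"]
  )
}

#' @rdname oxidation_rate
#' @export
glance.peatmob_oxidation <- function(x, ...) {
  tibble(
    rate = x$rate, slope = x$slope, r_squared = x$r_squared,
    dry_mass = x$dry_mass, n_timepoints = nrow(x$data)
  )
}

#' @rdname oxidation_rate
#' @param object A `peatmob_oxidation` object.
#' @export
autoplot.peatmob_oxidation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$mass_ug)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "incubation time (h)", y = expression("headspace CH"[4] ~ (mu * g)),
      subtitle = sprintf("%.1f ug CH4 g-1 dry soil d-1", object$rate)
    ) +
    ggplot2::theme_minimal()
}

#' Gravimetric soil water content
#'
#' @param wet_mass,dry_mass Masses in g, with `0 < dry_mass <= wet_mass`.
#' @return Water content as weight percent of wet mass.
#' @export
water_content <- function(wet_mass, dry_mass) {
  stopifnot(all(dry_mass > 0), all(dry_mass <= wet_mass))
  (wet_mass - dry_mass) / wet_mass * 100
}

#' Soil organic matter by loss on ignition
#'
#' @param dry_mass Dry mass before incineration, g.
#' @param ash_mass Mass remaining after incineration, g
#'   (`0 <= ash_mass <= dry_mass`).
#' @return Organic matter as weight percent of dry mass.
#' @export
soil_organic_matter <- function(dry_mass, ash_mass) {
  stopifnot(all(dry_mass > 0), all(ash_mass >= 0), all(ash_mass <= dry_mass))
  (dry_mass - ash_mass) / dry_mass * 100
}
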