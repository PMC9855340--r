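# Units throughout: S_k in U (cGy cm^2 h^-1), Lambda in cGy h^-1 U^-1,
# dose rate in cGy h^-1, dwell times in seconds (converted by /3600 before
# multiplying an hourly rate), dose in cGy.

#' One dwell position of the stepping source
#'
#' @param index ordinal of the dwell within the plan (unique).
#' @param geometry a [dwell_geometry()].
#' @param dwell_time_s dwell time in seconds (>= 0).
#' @param channel channel identifier (applicator lumen).
#' @return Object of class `"dwell_position"`.
#' @export
dwell_position <- function(index, geometry, dwell_time_s, channel = "1") {
  if (!is.numeric(index) || length(index) != 1L || index != round(index))
    bc_domain_error("dwell 'index' must be a single integer")
  if (!inherits(geometry, "dwell_geometry"))
    bc_domain_error("'geometry' must be a dwell_geometry")
  stopifnot_scalar_number(dwell_time_s, "dwell_time_s")
  if (dwell_time_s < 0) bc_domain_error("dwell_time_s must be >= 0")
  structure(list(index = as.integer(index), geometry = geometry,
                 dwell_time_s = as.double(dwell_time_s),
                 channel = as.character(channel)),
            class = "dwell_position")
}

#' Air-kerma strength calibration record
#'
#' Both dates are taken at midnight ("12 a.m."); the decay interval is the
#' whole-day calendar difference, not a fractional elapsed time. Sub-day decay
#' of Ir-192 (< 0.5%/day) is below the resolution of the acceptance band.
#'
#' @param Sk_calibration air-kerma strength at calibration, U (> 0).
#' @param calibration_date,treatment_date `Date`s or "YYYY-MM-DD" strings;
#'   treatment must not precede calibration.
#' @return Object of class `"kerma_calibration"`.
#' @export
kerma_calibration <- function(Sk_calibration, calibration_date, treatment_date) {
  stopifnot_scalar_number(Sk_calibration, "Sk_calibration")
  if (Sk_calibration <= 0) bc_domain_error("Sk_calibration must be > 0")
  cal <- as.Date(calibration_date)
  trt <- as.Date(treatment_date)
  if (is.na(cal) || is.na(trt))
    bc_stop("brachycheck_date_error", "calibration/treatment dates must be valid dates")
  if (trt < cal)
    bc_stop("brachycheck_date_error",
            sprintf("treatment date (%s) precedes calibration date (%s)", trt, cal))
  structure(list(Sk_calibration = as.double(Sk_calibration),
                 calibration_date = cal, treatment_date = trt),
            class = "kerma_calibration")
}

#' Decay the air-kerma strength to the treatment day
#'
#' \deqn{S_k(t) = S_{k,\mathrm{cal}} \cdot 2^{-\Delta t / T_{1/2}}}
#' with \eqn{\Delta t} the whole-day difference between treatment and
#' calibration dates at midnight.
#'
#' @param cal a [kerma_calibration()].
#' @param half_life_days radionuclide half-life in days (> 0).
#' @return Air-kerma strength on the treatment day, U.
#' @export
decay_air_kerma_strength <- function(cal, half_life_days) {
  if (!inherits(cal, "kerma_calibration"))
    bc_domain_error("'cal' must be a kerma_calibration")
  stopifnot_scalar_number(half_life_days, "half_life_days")
  if (half_life_days <= 0) bc_domain_error("half_life_days must be > 0")
  dt <- as.numeric(cal$treatment_date - cal$calibration_date)
  cal$Sk_calibration * 2^(-dt / half_life_days)
}

#' TG-43 2D dose rate of one dwell at a point
#'
#' The general 2D line-source formalism:
#' \deqn{\dot D(r,\theta) = S_k \Lambda
#'   \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)} g_L(r) F(r,\theta)}
#' with the reference normalization at r0 = 1 cm, theta0 = 90 degrees
#' evaluated for the same active length. Points on or inside the source
#' capsule (perpendicular distance to the source segment below
#' `capsule_radius_cm`) raise a near-source error. Evaluations outside the
#' fitted validity window \[`r_min`, `r_max`\] are flagged, not refused: the
#' fitted g and F forms are analytic everywhere but only accurate inside the
#' fit domain.
#'
#' @param spec a [source_spec()].
#' @param Sk air-kerma strength on the treatment day, U.
#' @param geom a [dwell_geometry()].
#' @param point 3-vector, cm.
#' @param r_min,r_max validity window of the fitted functions, cm.
#' @param capsule_radius_cm near-source guard radius, cm.
#' @param detail if `TRUE`, return the individual factors too.
#' @return Dose rate in cGy/h with attribute `flags` (character vector among
#'   `"near-source"`-fatal handled by error, `"near-field"`, `"far-field"`,
#'   `"clamped-theta"`); with `detail = TRUE` a list of all factors.
#' @export
dwell_dose_rate <- function(spec, Sk, geom, point,
                            r_min = 0.2, r_max = 10,
                            capsule_radius_cm = 0.05, detail = FALSE) {
  if (!inherits(spec, "source_spec")) bc_domain_error("'spec' must be a source_spec")
  stopifnot_scalar_number(Sk, "Sk")
  if (Sk <= 0) bc_domain_error("air-kerma strength Sk must be > 0")
  L <- spec$active_length_cm

  dist <- segment_distance(geom, point, L)
  if (dist < capsule_radius_cm)
    bc_near_source_error(sprintf(
      "point is %.4g cm from the source segment (inside the %.3g cm capsule guard)",
      dist, capsule_radius_cm), distance = dist)

  coords <- polar_coords(geom, point, L)
  GL <- geometry_function(coords, L)
  GL0 <- reference_geometry_function(L)
  g <- radial_dose(spec, coords$r)
  F_ <- anisotropy(spec, coords$r, coords$theta)

  flags <- character(0)
  if (coords$r < r_min) flags <- c(flags, "near-field")
  if (coords$r > r_max) flags <- c(flags, "far-field")
  if (attr(F_, "clamped")[1]) flags <- c(flags, "clamped-theta")

  rate <- Sk * spec$dose_rate_constant * (GL / GL0) * g * as.double(F_)
  if (!is.finite(rate))
    bc_numeric_error(sprintf("non-finite dose rate at r = %g cm, theta = %g deg",
                             coords$r, coords$theta))
  if (detail)
    return(list(rate_cGy_h = rate, r = coords$r, theta = coords$theta,
                beta = coords$beta, GL = GL, GL_ref = GL0, g = g,
                F = as.double(F_), flags = flags))
  structure(rate, flags = flags)
}

#' Total dose at a verification point from all dwells
#'
#' Sums the dwell dose rates weighted by their dwell times,
#' \eqn{D = \sum_i \dot D_i(r,\theta) \, t_i}, with times in seconds
#' converted to hours. A near-source failure at any dwell aborts the sum with
#' an error naming the offending dwell index and its distance.
#'
#' @inheritParams dwell_dose_rate
#' @param dwells non-empty list of [dwell_position()]s.
#' @return List with `dose_cGy`, `contributions_cGy` (one per dwell, plan
#'   order) and `flags` (union of per-dwell diagnostic flags).
#' @export
plan_dose <- function(spec, Sk, dwells, point,
                      r_min = 0.2, r_max = 10, capsule_radius_cm = 0.05) {
  if (!is.list(dwells) || length(dwells) == 0L)
    bc_stop("brachycheck_plan_error", "plan has no dwell positions")
  contributions <- numeric(length(dwells))
  flags <- character(0)
  for (i in seq_along(dwells)) {
    dw <- dwells[[i]]
    if (!inherits(dw, "dwell_position"))
      bc_stop("brachycheck_plan_error", sprintf("dwell %d is not a dwell_position", i))
    rate <- tryCatch(
      dwell_dose_rate(spec, Sk, dw$geometry, point,
                      r_min = r_min, r_max = r_max,
                      capsule_radius_cm = capsule_radius_cm),
      brachycheck_near_source_error = function(e)
        bc_near_source_error(
          sprintf("dwell %d (channel %s): %s", dw$index, dw$channel,
                  conditionMessage(e)),
          dwell_index = dw$index, distance = e$distance))
    contributions[i] <- as.double(rate) * dw$dwell_time_s / 3600
    flags <- union(flags, attr(rate, "flags"))
  }
  list(dose_cGy = sum(contributions), contributions_cGy = contributions,
       flags = flags)
}
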