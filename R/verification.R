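#' Named verification point with its planning-system dose
#'
#' @param name point label (e.g. "point A left", "bladder").
#' @param position 3-vector, cm.
#' @param tps_dose dose at the point computed by the treatment planning
#'   system, cGy (> 0 for a comparable point).
#' @param dose_source `"tps"` when the dose is the TPS-computed point dose,
#'   `"target"` when it is a prescription/target dose carried by the plan
#'   file (the report labels which was used).
#' @return Object of class `"verification_point"`.
#' @export
verification_point <- function(name, position, tps_dose,
                               dose_source = c("tps", "target")) {
  dose_source <- match.arg(dose_source)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    bc_domain_error("verification point 'name' must be a non-empty string")
  position <- vec3(position, "position")
  stopifnot_scalar_number(tps_dose, "tps_dose")
  if (tps_dose <= 0)
    bc_stop("brachycheck_comparison_error",
            sprintf("point '%s': tps_dose must be > 0 for a comparable point", name))
  structure(list(name = name, position = position,
                 tps_dose = as.double(tps_dose), dose_source = dose_source),
            class = "verification_point")
}

#' Relative dose difference in percent
#'
#' \deqn{D_{\mathrm{diff}\%} = 100\% \times (D_{\mathrm{check}} -
#'   D_{\mathrm{TPS}}) / D_{\mathrm{TPS}}}
#'
#' @param dvp_dose independently computed dose, cGy.
#' @param tps_dose planning-system dose, cGy (> 0).
#' @return Signed percent difference.
#' @export
relative_difference <- function(dvp_dose, tps_dose) {
  if (!is.numeric(dvp_dose) || !is.numeric(tps_dose) ||
      any(!is.finite(dvp_dose)) || any(!is.finite(tps_dose)))
    bc_stop("brachycheck_comparison_error", "doses must be finite numbers")
  if (any(tps_dose <= 0))
    bc_stop("brachycheck_comparison_error", "tps_dose must be > 0")
  100 * (dvp_dose - tps_dose) / tps_dose
}

#' Error-propagated acceptance half-width
#'
#' Combines the mean relative deviations of the fitted radial dose and
#' anisotropy functions from their reference data by linear error
#' propagation: \eqn{\Delta(g \cdot F) = \sqrt{\Delta g^2 + \Delta F^2}}.
#' With the GammaMed Plus Ir-192 deviations (0.5% and 0.9%) the half-width
#' is 1.03% at two-decimal display precision.
#'
#' @param delta_g mean relative deviation of g_L, percent (>= 0).
#' @param delta_F mean relative deviation of F, percent (>= 0).
#' @return Half-width of the symmetric acceptance interval, percent.
#' @export
acceptance_range <- function(delta_g, delta_F) {
  stopifnot_scalar_number(delta_g, "delta_g")
  stopifnot_scalar_number(delta_F, "delta_F")
  if (delta_g < 0 || delta_F < 0)
    bc_domain_error("fit deviations must be non-negative")
  sqrt(delta_g^2 + delta_F^2)
}

#' Acceptance band object
#'
#' @inheritParams acceptance_range
#' @return Object of class `"acceptance_band"` with fields `delta_g`,
#'   `delta_F` and `band` (the propagated half-width), all in percent.
#' @export
acceptance_band <- function(delta_g = 0.5, delta_F = 0.9) {
  structure(list(delta_g = as.double(delta_g), delta_F = as.double(delta_F),
                 band = acceptance_range(delta_g, delta_F)),
            class = "acceptance_band")
}

#' Default acceptance band of a source model
#'
#' Uses the fit deviations recorded in the source configuration when present,
#' falling back to the GammaMed Plus Ir-192 deviations (0.5%, 0.9%).
#'
#' @param spec a [source_spec()].
#' @return An [acceptance_band()].
#' @export
default_band <- function(spec) {
  if (inherits(spec, "source_spec") &&
      is.finite(spec$delta_g_percent) && is.finite(spec$delta_F_percent))
    acceptance_band(spec$delta_g_percent, spec$delta_F_percent)
  else acceptance_band()
}

#' Verify one point against the planning-system dose
#'
#' Computes the independent dose by [plan_dose()], the signed percent
#' difference, and the pass/fail judgement: a point passes when
#' `|diff_percent| <= band$band` (inclusive boundary) and no fatal
#' near-source diagnostic fired. Far-field and clamped-theta conditions are
#' warnings — the fitted functions lose accuracy there, so the report
#' surfaces them prominently, but they do not by themselves fail the point.
#' A near-source failure is converted into a failed result carrying the
#' diagnosis (batch verification continues past it).
#'
#' @inheritParams plan_dose
#' @param point a [verification_point()].
#' @param band an [acceptance_band()].
#' @return Object of class `"verification_result"`: list with `point`,
#'   `dvp_dose` (cGy, `NA` on a near-source failure), `diff_percent`,
#'   `passed`, `warnings` (diagnostic flags), `contributions` (per-dwell
#'   cGy) and `diagnostic` (message, or `NA`).
#' @export
verify_point <- function(spec, Sk, dwells, point, band = default_band(spec),
                         r_min = 0.2, r_max = 10, capsule_radius_cm = 0.05) {
  if (!inherits(point, "verification_point"))
    bc_domain_error("'point' must be a verification_point")
  if (!inherits(band, "acceptance_band"))
    bc_domain_error("'band' must be an acceptance_band")

  res <- tryCatch(
    plan_dose(spec, Sk, dwells, point$position,
              r_min = r_min, r_max = r_max,
              capsule_radius_cm = capsule_radius_cm),
    brachycheck_near_source_error = function(e) e)

  if (inherits(res, "brachycheck_near_source_error")) {
    return(structure(list(
      point = point, dvp_dose = NA_real_, diff_percent = NA_real_,
      passed = FALSE, warnings = "near-source",
      contributions = numeric(0),
      diagnostic = conditionMessage(res)), class = "verification_result"))
  }

  diff <- relative_difference(res$dose_cGy, point$tps_dose)
  structure(list(
    point = point, dvp_dose = res$dose_cGy, diff_percent = diff,
    passed = abs(diff) <= band$band, warnings = res$flags,
    contributions = res$contributions_cGy,
    diagnostic = NA_character_), class = "verification_result")
}

#' Verify every point of a plan
#'
#' Decays the plan's air-kerma strength to the treatment day, then runs
#' [verify_point()] for each (optionally filtered) verification point.
#'
#' @param plan a [brachy_plan()].
#' @param spec a [source_spec()]; by default loaded from the plan's
#'   `source_model_name` via [load_source_spec()].
#' @param band an [acceptance_band()]; defaults to the source model's.
#' @param points optional character vector of point names to verify.
#' @inheritParams plan_dose
#' @return Object of class `"verification_run"`: list with `plan_id`,
#'   `source_name`, `Sk_treatment` (U), `band` and `results`.
#' @export
verify_plan <- function(plan, spec = NULL, band = NULL, points = NULL,
                        r_min = 0.2, r_max = 10, capsule_radius_cm = 0.05) {
  if (!inherits(plan, "brachy_plan")) bc_domain_error("'plan' must be a brachy_plan")
  if (is.null(spec)) spec <- load_source_spec(plan$source_model_name)
  if (is.null(band)) band <- default_band(spec)
  sel <- plan$points
  if (!is.null(points)) {
    keep <- vapply(sel, function(p) p$name %in% points, logical(1))
    if (!any(keep))
      bc_stop("brachycheck_plan_error",
              sprintf("no verification point matches: %s",
                      paste(points, collapse = ", ")))
    sel <- sel[keep]
  }
  if (length(sel) == 0L)
    bc_stop("brachycheck_plan_error", "plan has no verification points")
  Sk <- decay_air_kerma_strength(plan$calibration, spec$half_life_days)
  results <- lapply(sel, function(p)
    verify_point(spec, Sk, plan$dwells, p, band = band,
                 r_min = r_min, r_max = r_max,
                 capsule_radius_cm = capsule_radius_cm))
  structure(list(plan_id = plan$plan_id, source_name = spec$name,
                 Sk_treatment = Sk, band = band, results = results),
            class = "verification_run")
}

#' @export
print.verification_run <- function(x, ...) {
  writeLines(build_report(x))
  invisible(x)
}

#' Assemble the plain-text verification report
#'
#' Lists the plan identifiers, the decayed air-kerma strength, the acceptance
#' band, and for each point the independent dose, the planning-system dose,
#' the signed percent difference (two decimals in display; all comparisons
#' internally use full precision), the PASS/FAIL judgement with any
#' diagnostics, and the per-dwell dose contributions.
#'
#' @param run a `verification_run` from [verify_plan()].
#' @return Character vector of report lines (class `"verification_report"`).
#' @export
build_report <- function(run) {
  if (!inherits(run, "verification_run"))
    bc_domain_error("'run' must be a verification_run")
  if (length(run$results) == 0L)
    bc_stop("brachycheck_plan_error", "nothing to report: no verification results")
  lines <- c(
    "Independent dose verification report (TG-43U1 2D line source)",
    sprintf("plan: %s    source model: %s", run$plan_id, run$source_name),
    sprintf("S_k on treatment day: %.2f U", run$Sk_treatment),
    sprintf("acceptance band: +/-%.2f%% (delta_g %.2f%%, delta_F %.2f%%)",
            run$band$band, run$band$delta_g, run$band$delta_F),
    "")
  for (res in run$results) {
    status <- if (res$passed) "PASS" else "FAIL"
    lines <- c(lines, sprintf("[%s] %s  (%.3f, %.3f, %.3f) cm  [%s dose]",
                              status, res$point$name,
                              res$point$position[1], res$point$position[2],
                              res$point$position[3], res$point$dose_source))
    if (is.na(res$dvp_dose)) {
      lines <- c(lines, sprintf("    %s", res$diagnostic))
    } else {
      lines <- c(lines, sprintf(
        "    D_check = %.4f cGy   D_TPS = %.4f cGy   D_diff = %+.2f%%",
        res$dvp_dose, res$point$tps_dose, res$diff_percent))
      if (length(res$contributions))
        lines <- c(lines, sprintf("    per-dwell contributions (cGy): %s",
                                  paste(sprintf("%.4f", res$contributions),
                                        collapse = " ")))
    }
    if (length(res$warnings))
      lines <- c(lines, sprintf("    warnings: %s",
                                paste(res$warnings, collapse = ", ")))
  }
  structure(lines, class = c("verification_report", "character"))
}

#' Write the structured (JSON) verification report
#'
#' Machine-readable export of the same content as the text report: one record
#' per verification point with the nested per-dwell contribution list.
#' [read_report_json()] restores it.
#'
#' @param run a `verification_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(run, path) {
  if (!inherits(run, "verification_run"))
    bc_domain_error("'run' must be a verification_run")
  doc <- list(
    plan_id = run$plan_id,
    source_model = run$source_name,
    Sk_treatment_U = run$Sk_treatment,
    band_percent = list(delta_g = run$band$delta_g, delta_F = run$band$delta_F,
                        band = run$band$band),
    points = lapply(run$results, function(res) list(
      name = res$point$name,
      position_cm = res$point$position,
      dose_source = res$point$dose_source,
      tps_dose_cGy = res$point$tps_dose,
      dvp_dose_cGy = res$dvp_dose,
      diff_percent = res$diff_percent,
      passed = res$passed,
      warnings = as.list(res$warnings),
      diagnostic = res$diagnostic,
      contributions_cGy = as.list(res$contributions))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a structured verification report
#'
#' @param path a JSON file written by [write_report_json()].
#' @return A `verification_run` equivalent to the one exported.
#' @export
read_report_json <- function(path) {
  doc <- jsonlite::read_json(path)
  results <- lapply(doc$points, function(p) {
    pt <- verification_point(p$name, unlist(p$position_cm), p$tps_dose_cGy,
                             dose_source = p$dose_source)
    structure(list(
      point = pt,
      dvp_dose = if (is.null(p$dvp_dose_cGy)) NA_real_ else p$dvp_dose_cGy,
      diff_percent = if (is.null(p$diff_percent)) NA_real_ else p$diff_percent,
      passed = isTRUE(p$passed),
      warnings = as.character(unlist(p$warnings)),
      contributions = as.double(unlist(p$contributions_cGy)),
      diagnostic = if (is.null(p$diagnostic)) NA_character_ else p$diagnostic),
      class = "verification_result")
  })
  structure(list(plan_id = doc$plan_id, source_name = doc$source_model,
                 Sk_treatment = doc$Sk_treatment_U,
                 band = acceptance_band(doc$band_percent$delta_g,
                                        doc$band_percent$delta_F),
                 results = results),
            class = "verification_run")
}
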