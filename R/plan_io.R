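#' Brachytherapy plan container
#'
#' Calibration, dwell positions and verification points of one HDR plan, all
#' positions in a single patient coordinate frame and stored in cm.
#'
#' @param plan_id plan label.
#' @param source_model_name name of the source model used by the plan.
#' @param calibration a [kerma_calibration()].
#' @param dwells list of [dwell_position()]s (non-empty for a verifiable plan).
#' @param points list of [verification_point()]s.
#' @return Object of class `"brachy_plan"`.
#' @export
brachy_plan <- function(plan_id, source_model_name, calibration,
                        dwells, points = list()) {
  if (!is.character(plan_id) || length(plan_id) != 1L)
    bc_domain_error("'plan_id' must be a single string")
  if (!inherits(calibration, "kerma_calibration"))
    bc_domain_error("'calibration' must be a kerma_calibration")
  if (!is.list(dwells) ||
      !all(vapply(dwells, inherits, logical(1), "dwell_position")))
    bc_domain_error("'dwells' must be a list of dwell_position objects")
  idx <- vapply(dwells, `[[`, integer(1), "index")
  if (anyDuplicated(idx))
    bc_stop("brachycheck_plan_error", "dwell indices must be unique within a plan")
  if (!is.list(points) ||
      !all(vapply(points, inherits, logical(1), "verification_point")))
    bc_domain_error("'points' must be a list of verification_point objects")
  structure(list(plan_id = plan_id,
                 source_model_name = as.character(source_model_name),
                 calibration = calibration, dwells = dwells, points = points),
            class = "brachy_plan")
}

#' @export
print.brachy_plan <- function(x, ...) {
  cat(sprintf("Brachytherapy plan '%s' (source model %s)\n",
              x$plan_id, x$source_model_name))
  cat(sprintf("  S_k at calibration: %.2f U (%s), treatment %s\n",
              x$calibration$Sk_calibration,
              x$calibration$calibration_date, x$calibration$treatment_date))
  cat(sprintf("  %d dwell positions in %d channel(s), %d verification point(s)\n",
              length(x$dwells),
              length(unique(vapply(x$dwells, `[[`, character(1), "channel"))),
              length(x$points)))
  invisible(x)
}

# ---- portable text dialect -------------------------------------------------
# YAML document with explicit center + orientation per dwell (the content of
# the planning system's per-dwell transform matrix), all lengths in cm. This
# sidesteps any channel-geometry derivation: the text dialect is the faithful
# carrier of dwell orientation.

plan_required <- function(x, field, where) {
  if (is.null(x[[field]]))
    bc_format_error(sprintf("plan document: missing field '%s' in %s", field, where))
  x[[field]]
}

#' Write a plan to the portable text dialect
#'
#' @param plan a [brachy_plan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_plan_text()] for the schema.
#' @export
write_plan_text <- function(plan, path) {
  if (!inherits(plan, "brachy_plan")) bc_domain_error("'plan' must be a brachy_plan")
  doc <- list(
    format = "brachycheck-plan/1",
    plan_id = plan$plan_id,
    source_model = plan$source_model_name,
    calibration = list(
      sk_U = plan$calibration$Sk_calibration,
      calibration_date = format(plan$calibration$calibration_date),
      treatment_date = format(plan$calibration$treatment_date)),
    dwells = lapply(plan$dwells, function(d) list(
      index = d$index, channel = d$channel, time_s = d$dwell_time_s,
      center_cm = d$geometry$center, orientation = d$geometry$orientation)),
    points = lapply(plan$points, function(p) list(
      name = p$name, position_cm = p$position, tps_dose_cGy = p$tps_dose,
      dose_source = p$dose_source)))
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a plan from the portable text dialect
#'
#' The dialect is a YAML document: `plan_id`, `source_model`, `calibration`
#' (`sk_U`, `calibration_date`, `treatment_date`), `dwells` (each with
#' `index`, `channel`, `time_s`, `center_cm` and `orientation`, lengths in
#' cm) and `points` (each with `name`, `position_cm`, `tps_dose_cGy` and
#' optional `dose_source`). The round trip through [write_plan_text()] is
#' lossless.
#'
#' @param path plan file path.
#' @return A [brachy_plan()].
#' @export
read_plan_text <- function(path) {
  if (!file.exists(path)) bc_format_error(sprintf("file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) bc_format_error(
                    sprintf("cannot parse plan '%s': %s", path, conditionMessage(e))))
  cal <- plan_required(doc, "calibration", "plan")
  calibration <- kerma_calibration(
    plan_required(cal, "sk_U", "calibration"),
    plan_required(cal, "calibration_date", "calibration"),
    plan_required(cal, "treatment_date", "calibration"))
  dwells <- lapply(seq_along(doc$dwells), function(i) {
    d <- doc$dwells[[i]]
    where <- sprintf("dwell %d", i)
    dwell_position(
      index = plan_required(d, "index", where),
      geometry = dwell_geometry(unlist(plan_required(d, "center_cm", where)),
                                unlist(plan_required(d, "orientation", where))),
      dwell_time_s = plan_required(d, "time_s", where),
      channel = if (is.null(d$channel)) "1" else d$channel)
  })
  points <- lapply(seq_along(doc$points), function(i) {
    p <- doc$points[[i]]
    where <- sprintf("point %d", i)
    verification_point(
      name = plan_required(p, "name", where),
      position = unlist(plan_required(p, "position_cm", where)),
      tps_dose = plan_required(p, "tps_dose_cGy", where),
      dose_source = if (is.null(p$dose_source)) "tps" else p$dose_source)
  })
  brachy_plan(plan_id = plan_required(doc, "plan_id", "plan"),
              source_model_name = plan_required(doc, "source_model", "plan"),
              calibration = calibration, dwells = dwells, points = points)
}

# ---- DICOM RT Plan ---------------------------------------------------------

# Orientation of each dwell from the channel polyline: normalized central
# difference of the neighbouring *distinct* positions (forward/backward at
# the channel ends). The RT Plan brachy module stores positions only; the
# tangent of the source train is the physical orientation of the source.
channel_orientations <- function(positions, default_axis = c(0, 0, 1)) {
  n <- nrow(positions)
  out <- matrix(NA_real_, n, 3)
  distinct_prev <- function(i) {
    for (j in rev(seq_len(i - 1)))
      if (sum((positions[j, ] - positions[i, ])^2) > 1e-16) return(j)
    NA_integer_
  }
  distinct_next <- function(i) {
    for (j in seq.int(i + 1, length.out = max(n - i, 0)))
      if (sum((positions[j, ] - positions[i, ])^2) > 1e-16) return(j)
    NA_integer_
  }
  for (i in seq_len(n)) {
    p <- distinct_prev(i); q <- distinct_next(i)
    v <- if (!is.na(p) && !is.na(q)) positions[q, ] - positions[p, ]
         else if (!is.na(q)) positions[q, ] - positions[i, ]
         else if (!is.na(p)) positions[i, ] - positions[p, ]
         else default_axis
    nrm <- sqrt(sum(v^2))
    out[i, ] <- if (nrm > 0) v / nrm else default_axis
  }
  out
}

#' Read a brachytherapy DICOM RT Plan
#'
#' Flattens the application setup / channel / brachy control point hierarchy
#' into dwell positions. Dwell times are recovered from the channel total
#' time and the cumulative time weights: interval i between consecutive
#' control points gets `total_time * (w[i+1] - w[i]) / w_final` seconds at
#' the position of its end control point (zero-length movement intervals are
#' kept as zero-time dwells). Control-point positions (mm, DICOM patient
#' coordinates) are converted to cm; dwell orientations are derived from the
#' channel polyline tangent. Dose reference points with 3D coordinates become
#' verification points; their dose is the target prescription dose the plan
#' carries (labelled `"target"` — override with the text dialect's
#' authoritative `tps_dose` when a TPS-computed point dose is available).
#'
#' @param path DICOM RT Plan file (explicit VR little endian).
#' @param source_model name of the source model to associate with the plan.
#' @param default_axis orientation for single-dwell channels, where no
#'   tangent is defined.
#' @return A [brachy_plan()].
#' @export
read_rtplan_dicom <- function(path, source_model = "GammaMedPlus-Ir192",
                              default_axis = c(0, 0, 1)) {
  ds <- read_dicom(path)
  sop <- dcm_get(ds, "00080016")
  if (is.null(sop) || !identical(sop, DCM_RTPLAN_SOP))
    bc_format_error(sprintf(
      "'%s' is not an RT Plan (SOP class %s)", path,
      if (is.null(sop)) "missing" else sop))

  setups <- dcm_get(ds, "300A0230")
  if (is.null(setups) || length(setups) == 0L)
    bc_format_error("RT Plan has no brachy application setup sequence")

  src_seq <- dcm_get(ds, "300A0210")
  if (is.null(src_seq) || length(src_seq) == 0L)
    bc_format_error("RT Plan has no source sequence")
  src <- src_seq[[1]]
  half_life <- dcm_get(src, "300A0226")
  rakr <- dcm_get(src, "300A022A")   # reference air kerma rate == S_k in U
  cal_date <- dcm_date(dcm_get(src, "300A022C"))
  if (is.null(rakr)) bc_format_error("source sequence lacks reference air kerma rate")
  if (is.null(cal_date)) bc_format_error("source sequence lacks source strength reference date")
  plan_date <- dcm_date(dcm_get(ds, "300A0006"))
  if (is.null(plan_date)) plan_date <- cal_date
  calibration <- kerma_calibration(rakr, cal_date, plan_date)

  dwells <- list()
  idx <- 0L
  for (setup in setups) {
    channels <- dcm_get(setup, "300A0280")
    if (is.null(channels)) next
    for (ch in channels) {
      ch_id <- as.character(dcm_get(ch, "300A0282", length(dwells) + 1L))
      total_time <- dcm_get(ch, "300A0286")
      final_w <- dcm_get(ch, "300A02C8")
      cps <- dcm_get(ch, "300A02D0")
      if (is.null(total_time) || is.null(cps) || length(cps) < 2L)
        bc_format_error(sprintf(
          "channel %s: needs a channel total time and at least two brachy control points", ch_id))
      w <- vapply(cps, function(cp) {
        v <- dcm_get(cp, "300A02D6")
        if (is.null(v)) bc_format_error(sprintf(
          "channel %s: control point lacks a cumulative time weight", ch_id))
        v
      }, numeric(1))
      pos <- t(vapply(cps, function(cp) {
        v <- dcm_get(cp, "300A02D4")
        if (is.null(v) || length(v) != 3L) bc_format_error(sprintf(
          "channel %s: control point lacks a 3D position", ch_id))
        v
      }, numeric(3))) / 10  # mm -> cm
      if (is.null(final_w)) final_w <- w[length(w)]
      if (!is.finite(final_w) || final_w <= 0)
        bc_format_error(sprintf(
          "channel %s: final cumulative time weight must be > 0", ch_id))
      if (any(diff(w) < -1e-9))
        bc_format_error(sprintf(
          "channel %s: cumulative time weights must be non-decreasing", ch_id))
      times <- total_time * diff(w) / final_w
      dpos <- pos[-1, , drop = FALSE]           # interval i ends at CP i+1
      orient <- channel_orientations(dpos, default_axis)
      for (i in seq_along(times)) {
        idx <- idx + 1L
        dwells[[idx]] <- dwell_position(
          index = idx,
          geometry = dwell_geometry(dpos[i, ], orient[i, ]),
          dwell_time_s = times[i], channel = ch_id)
      }
    }
  }
  if (length(dwells) == 0L)
    bc_format_error("RT Plan contains no dwell positions")

  points <- list()
  for (ref in dcm_get(ds, "300A0010", list())) {
    coords <- dcm_get(ref, "300A0018")
    dose_gy <- dcm_get(ref, "300A0026")
    if (is.null(coords) || length(coords) != 3L || is.null(dose_gy)) next
    nm <- dcm_get(ref, "300A0016", sprintf("point %d", length(points) + 1L))
    points[[length(points) + 1L]] <-
      verification_point(nm, coords / 10, dose_gy * 100, dose_source = "target")
  }

  brachy_plan(plan_id = dcm_get(ds, "300A0002", basename(path)),
              source_model_name = source_model,
              calibration = calibration, dwells = dwells, points = points)
}

# ---- synthetic plan generator ---------------------------------------------

#' Default settings for the synthetic plan generator
#'
#' The defaults emulate a gynaecological HDR insertion: a tandem along the
#' patient axis (optionally flanked by two ovoid channels), dwell steps of
#' 0.5 cm, dwell times of 10-40 s, a 10 Ci-class source (40700 U) and four
#' ICRU-38-style verification points (point A left/right, bladder, rectum).
#'
#' @return Named list of generator settings; override any subset via the
#'   `config` argument of [generate_synthetic_plan()].
#' @export
synthetic_plan_defaults <- function() {
  list(style = "straight-tandem",   # or "tandem-ovoid"
       n_dwells = 5L,               # per channel
       step_cm = 0.5,
       time_range_s = c(10, 40),
       sk_U = 40700,
       calibration_date = "2026-09-01",
       max_elapsed_days = 30L,
       source_model = "GammaMedPlus-Ir192",
       tps_from_engine = TRUE,      # fill tps_dose with the engine's output
       tps_bias = 0,                # fractional bias applied to tps_dose
       point_jitter_cm = 0.2)
}

#' Generate a synthetic brachytherapy plan
#'
#' Deterministic for a fixed seed. `style = "straight-tandem"` places one
#' straight channel along +z with dwells every `step_cm`; `"tandem-ovoid"`
#' adds two short ovoid channels lateral to the tandem, with dwell
#' orientations tangent to each channel curve. Four verification points are
#' placed in the classical gynaecological arrangement relative to the tandem
#' (point A 2 cm up / 2 cm lateral on each side, a bladder point anterior, a
#' rectum point posterior), with a small seeded jitter. When
#' `tps_from_engine` is `TRUE` the TPS dose of each point is filled with the
#' engine's own output times `(1 + tps_bias)`, which makes the plan
#' self-consistent at zero bias and a controlled failure case otherwise.
#'
#' @param config list overriding entries of [synthetic_plan_defaults()].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A [brachy_plan()].
#' @examples
#' plan <- generate_synthetic_plan(seed = 1)
#' verify_plan(plan)
#' @export
generate_synthetic_plan <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(synthetic_plan_defaults(), config)
  if (!cfg$style %in% c("straight-tandem", "tandem-ovoid"))
    bc_config_error(sprintf("unknown applicator style '%s'", cfg$style))
  if (!is.numeric(cfg$n_dwells) || cfg$n_dwells < 1)
    bc_config_error("n_dwells must be >= 1")
  if (!is.numeric(cfg$step_cm) || cfg$step_cm <= 0)
    bc_config_error("step_cm must be > 0")
  if (length(cfg$time_range_s) != 2L || any(cfg$time_range_s < 0) ||
      diff(cfg$time_range_s) < 0)
    bc_config_error("time_range_s must be a non-decreasing pair of times >= 0")

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n <- as.integer(cfg$n_dwells)
  rt <- function(k) stats::runif(k, cfg$time_range_s[1], cfg$time_range_s[2])

  channels <- list()
  # tandem: straight along +z from the origin (cervical os at z = 0)
  z <- (seq_len(n) - 1) * cfg$step_cm
  channels$tandem <- list(centers = cbind(0, 0, z),
                          orientations = matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                          times = rt(n))
  if (cfg$style == "tandem-ovoid") {
    # ovoids: short arcs flanking the tandem, tilted outward in the x-z plane
    n_ov <- max(2L, min(n, 3L))
    for (side in c(-1, 1)) {
      s <- (seq_len(n_ov) - 1) * cfg$step_cm
      tilt <- 25 * pi / 180
      dir <- c(side * sin(tilt), 0, cos(tilt))
      base <- c(side * 1.5, 0, -0.5)
      centers <- t(vapply(s, function(si) base + si * dir, numeric(3)))
      channels[[if (side < 0) "ovoid-left" else "ovoid-right"]] <-
        list(centers = centers,
             orientations = matrix(dir, n_ov, 3, byrow = TRUE),
             times = rt(n_ov))
    }
  }

  dwells <- list(); idx <- 0L
  for (ch_name in names(channels)) {
    ch <- channels[[ch_name]]
    for (i in seq_len(nrow(ch$centers))) {
      idx <- idx + 1L
      dwells[[idx]] <- dwell_position(
        index = idx,
        geometry = dwell_geometry(ch$centers[i, ], ch$orientations[i, ]),
        dwell_time_s = ch$times[i], channel = ch_name)
    }
  }

  jit <- function() stats::runif(3, -cfg$point_jitter_cm, cfg$point_jitter_cm)
  point_defs <- list(
    `point A left`  = c(-2, 0, 2) + jit(),
    `point A right` = c(2, 0, 2) + jit(),
    bladder         = c(0, 2, 1) + jit(),
    rectum          = c(0, -2.5, 1) + jit())

  elapsed <- sample.int(cfg$max_elapsed_days + 1L, 1L) - 1L
  calibration <- kerma_calibration(
    cfg$sk_U, as.Date(cfg$calibration_date),
    as.Date(cfg$calibration_date) + elapsed)

  spec <- load_source_spec(cfg$source_model)
  Sk <- decay_air_kerma_strength(calibration, spec$half_life_days)
  points <- lapply(names(point_defs), function(nm) {
    pos <- point_defs[[nm]]
    dose <- if (isTRUE(cfg$tps_from_engine))
      plan_dose(spec, Sk, dwells, pos)$dose_cGy * (1 + cfg$tps_bias)
    else 600  # nominal fractional prescription, cGy
    verification_point(nm, pos, dose, dose_source = "tps")
  })

  brachy_plan(plan_id = sprintf("synthetic-%s-seed%d", cfg$style, as.integer(seed)),
              source_model_name = cfg$source_model,
              calibration = calibration, dwells = dwells, points = points)
}
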