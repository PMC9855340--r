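#' Coefficient quad for the anisotropy-function polynomials
#'
#' The 2D anisotropy function is built from radial coefficient functions of
#' the common form \eqn{c(r) = c_1 r^{c_2} + c_3 r + c_4}: a power term, a
#' linear term and a constant. One such quad exists for each of k, a, b, e
#' and the primed a', b', e' sets. Table entries that the source model does
#' not use are exactly zero.
#'
#' @param c1 coefficient of the power term.
#' @param c2 exponent of the power term (dimensionless).
#' @param c3 coefficient of the linear term.
#' @param c4 constant term.
#' @return A named numeric vector of length 4 with class `"coefficient_quad"`.
#' @examples
#' q <- coefficient_quad(-2.30569, -1.98e-2, 2.847e-2, 2.27378)
#' eval_coefficient(1, q)
#' @export
coefficient_quad <- function(c1 = 0, c2 = 0, c3 = 0, c4 = 0) {
  q <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4)
  if (!is.numeric(q) || length(q) != 4L || !all(is.finite(q)))
    bc_config_error("a coefficient quad needs four finite numbers (c1, c2, c3, c4)")
  structure(as.double(q), names = c("c1", "c2", "c3", "c4"),
            class = "coefficient_quad")
}

as_quad <- function(x, field) {
  if (inherits(x, "coefficient_quad")) return(x)
  if (is.list(x)) x <- unlist(x, use.names = FALSE)
  if (!is.numeric(x) || length(x) != 4L)
    bc_config_error(sprintf("field '%s' must be a numeric 4-vector (c1..c4)", field))
  coefficient_quad(x[[1]], x[[2]], x[[3]], x[[4]])
}

#' Evaluate a coefficient polynomial at a radius
#'
#' Computes \eqn{c_1 r^{c_2} + c_3 r + c_4}. A zero exponent means a constant
#' power term (`c1 * r^0 == c1` for all r > 0), matching the convention that
#' absent table entries are zeros.
#'
#' @param r radius in cm, strictly positive (vectorized).
#' @param quad a [coefficient_quad()] (or numeric 4-vector c1..c4).
#' @return Numeric vector, same length as `r`.
#' @export
eval_coefficient <- function(r, quad) {
  quad <- as_quad(quad, "quad")
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    bc_domain_error("radius 'r' must be finite and > 0")
  quad[[1]] * r^quad[[2]] + quad[[3]] * r + quad[[4]]
}

#' Source model: physical and fitted dosimetric parameters of a line source
#'
#' Bundles the physical description of an HDR line source (active length L,
#' dose rate constant Lambda, half-life) with the fitted analytic parameters
#' of its radial dose function \eqn{g_L(r) = h r^i / (1 + j r^k)} and 2D
#' anisotropy function (seven coefficient quads). The radial dose function is
#' normalized near the TG-43 reference point: the constructor rejects
#' parameter sets for which \eqn{g_L(1\,\mathrm{cm})} deviates from 1 by more
#' than 0.5%.
#'
#' @param name identifier of the source model.
#' @param active_length_cm active length L in cm (> 0).
#' @param dose_rate_constant dose rate constant Lambda in cGy h^-1 U^-1 (> 0).
#' @param half_life_days radionuclide half-life in days (> 0).
#' @param radial named list or vector with elements `h`, `i`, `j`, `k`.
#' @param anisotropy named list with coefficient quads `k`, `a`, `b`, `e`,
#'   `a_prime`, `b_prime`, `e_prime` (each a 4-vector c1..c4).
#' @param delta_g_percent,delta_F_percent average relative deviations (in %)
#'   of the fitted radial dose and anisotropy functions from the reference
#'   Monte Carlo data; they set the default acceptance band for this source.
#' @return An object of class `"source_spec"`.
#' @seealso [load_source_spec()], [radial_dose()], [anisotropy()]
#' @export
source_spec <- function(name, active_length_cm, dose_rate_constant,
                        half_life_days, radial, anisotropy,
                        delta_g_percent = NA_real_, delta_F_percent = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    bc_config_error("source model 'name' must be a non-empty string")
  stopifnot_scalar_number(active_length_cm, "active_length_cm")
  stopifnot_scalar_number(dose_rate_constant, "dose_rate_constant")
  stopifnot_scalar_number(half_life_days, "half_life_days")
  if (active_length_cm <= 0) bc_config_error("active_length_cm must be > 0")
  if (dose_rate_constant <= 0) bc_config_error("dose_rate_constant must be > 0")
  if (half_life_days <= 0) bc_config_error("half_life_days must be > 0")

  radial <- unlist(radial)
  for (f in c("h", "i", "j", "k"))
    if (!f %in% names(radial) || !is.finite(radial[[f]]))
      bc_config_error(sprintf("radial dose parameter '%s' is missing or not finite", f))
  radial <- radial[c("h", "i", "j", "k")]

  quads <- lapply(c(k = "k", a = "a", b = "b", e = "e", a_prime = "a_prime",
                    b_prime = "b_prime", e_prime = "e_prime"),
                  function(f) {
                    if (is.null(anisotropy[[f]]))
                      bc_config_error(sprintf("anisotropy quad '%s' is missing", f))
                    as_quad(anisotropy[[f]], f)
                  })

  spec <- structure(
    list(name = name,
         active_length_cm = as.double(active_length_cm),
         dose_rate_constant = as.double(dose_rate_constant),
         half_life_days = as.double(half_life_days),
         radial = radial,
         anisotropy = quads,
         delta_g_percent = as.double(delta_g_percent),
         delta_F_percent = as.double(delta_F_percent)),
    class = "source_spec")

  g1 <- radial_dose(spec, 1)
  if (abs(g1 - 1) > 0.005)
    bc_config_error(sprintf(
      "radial dose function is not normalized: g_L(1 cm) = %.5f deviates from 1 by more than 0.5%%", g1))
  spec
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf("Source model '%s'\n", x$name))
  cat(sprintf("  active length L: %.4g cm\n", x$active_length_cm))
  cat(sprintf("  dose rate constant Lambda: %.4g cGy/h/U\n", x$dose_rate_constant))
  cat(sprintf("  half-life: %.4g days\n", x$half_life_days))
  cat(sprintf("  radial dose g_L(r) = h r^i / (1 + j r^k): h=%.6g i=%.6g j=%.6g k=%.6g\n",
              x$radial[["h"]], x$radial[["i"]], x$radial[["j"]], x$radial[["k"]]))
  cat("  anisotropy coefficient quads (c1, c2, c3, c4):\n")
  for (f in names(x$anisotropy))
    cat(sprintf("    %-8s %s\n", f,
                paste(formatC(unclass(x$anisotropy[[f]]), format = "g", digits = 6),
                      collapse = "  ")))
  if (is.finite(x$delta_g_percent) && is.finite(x$delta_F_percent))
    cat(sprintf("  fit deviations: delta_g = %.2f%%, delta_F = %.2f%% (band %.2f%%)\n",
                x$delta_g_percent, x$delta_F_percent,
                acceptance_range(x$delta_g_percent, x$delta_F_percent)))
  invisible(x)
}

#' Radial dose function g_L(r)
#'
#' Analytic transverse-axis falloff beyond the geometry factor,
#' \eqn{g_L(r) = h r^i / (1 + j r^k)}, normalized so that
#' \eqn{g_L(r_0 = 1\,\mathrm{cm}) \approx 1}.
#'
#' @param spec a [source_spec()].
#' @param r radius in cm, > 0 (vectorized).
#' @return Dimensionless numeric vector.
#' @export
radial_dose <- function(spec, r) {
  if (!inherits(spec, "source_spec")) bc_domain_error("'spec' must be a source_spec")
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    bc_domain_error("radius 'r' must be finite and > 0")
  p <- spec$radial
  g <- p[["h"]] * r^p[["i"]] / (1 + p[["j"]] * r^p[["k"]])
  if (any(!is.finite(g)))
    bc_numeric_error(sprintf("radial dose function non-finite at r = %g cm",
                             r[which(!is.finite(g))[1]]))
  g
}

# Polar angles are clamped away from the exact source axis before the fitted
# anisotropy form is evaluated: u^e and (1-u)^e' diverge at u = 0 or 1 when an
# exponent is negative. The fit is a smooth surrogate and is never needed at
# the exact poles (the geometry function carries its own collinear branch).
THETA_MIN_DEG <- 0.05

#' 2D anisotropy function F(r, theta)
#'
#' Angular dose variation around the line source relative to the transverse
#' axis (theta0 = 90 deg), evaluated from fitted coefficient polynomials:
#' \deqn{F(r,\theta) = k(r) + \frac{a(r) u^{e(r)}}{1 + b(r) u^{e(r)}}
#'   + \frac{a'(r) (1-u)^{e'(r)}}{1 + b'(r)(1-u)^{e'(r)}}, \quad u = \theta/180.}
#' Angles within `theta_min` of 0 or 180 degrees are clamped to the nearest
#' admissible angle; the returned vector carries a logical `"clamped"`
#' attribute so callers can surface the clamp as a diagnostic.
#'
#' @param spec a [source_spec()].
#' @param r radius in cm, > 0 (recycled against `theta`).
#' @param theta polar angle in degrees, in \[0, 180\].
#' @param theta_min clamp margin in degrees (default 0.05).
#' @return Dimensionless numeric vector with attribute `clamped`.
#' @export
anisotropy <- function(spec, r, theta, theta_min = THETA_MIN_DEG) {
  if (!inherits(spec, "source_spec")) bc_domain_error("'spec' must be a source_spec")
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    bc_domain_error("radius 'r' must be finite and > 0")
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta < 0) || any(theta > 180))
    bc_domain_error("'theta' must lie in [0, 180] degrees")

  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  clamped <- theta < theta_min | theta > 180 - theta_min
  theta <- pmin(pmax(theta, theta_min), 180 - theta_min)
  u <- theta / 180

  q <- spec$anisotropy
  kr <- eval_coefficient(r, q$k)
  ar <- eval_coefficient(r, q$a);  br <- eval_coefficient(r, q$b)
  er <- eval_coefficient(r, q$e)
  apr <- eval_coefficient(r, q$a_prime); bpr <- eval_coefficient(r, q$b_prime)
  epr <- eval_coefficient(r, q$e_prime)

  t1 <- u^er; t2 <- (1 - u)^epr
  val <- kr + ar * t1 / (1 + br * t1) + apr * t2 / (1 + bpr * t2)
  if (any(!is.finite(val))) {
    i <- which(!is.finite(val))[1]
    bc_numeric_error(sprintf(
      "anisotropy function non-finite at r = %g cm, theta = %g deg (denominator singularity)",
      r[i], theta[i]), r = r[i], theta = theta[i])
  }
  attr(val, "clamped") <- clamped
  val
}

# ---- source model registry -------------------------------------------------

builtin_source_dir <- function()
  system.file("extdata", "sources", package = "brachycheck")

#' List the built-in source models
#'
#' @return Character vector of names accepted by [load_source_spec()].
#' @export
list_source_models <- function() {
  files <- list.files(builtin_source_dir(), pattern = "\\.ya?ml$")
  sort(sub("\\.ya?ml$", "", files))
}

#' Load a source model from the built-in registry or a configuration file
#'
#' The configuration is a YAML document with fields `name`,
#' `active_length_cm`, `dose_rate_constant`, `half_life_days`, `radial`
#' (`h`, `i`, `j`, `k`) and `anisotropy` (seven 4-vectors ordered c1..c4:
#' `k`, `a`, `b`, `e`, `a_prime`, `b_prime`, `e_prime`), plus optional
#' `delta_g_percent` / `delta_F_percent` fit deviations. The GammaMed Plus
#' HDR Ir-192 model ships built in as `"GammaMedPlus-Ir192"`.
#'
#' @param source name of a built-in model or path to a YAML configuration.
#' @return A validated [source_spec()].
#' @examples
#' spec <- load_source_spec("GammaMedPlus-Ir192")
#' radial_dose(spec, 1)
#' @export
load_source_spec <- function(source = "GammaMedPlus-Ir192") {
  if (!is.character(source) || length(source) != 1L)
    bc_config_error("'source' must be a model name or a file path")
  path <- source
  if (!file.exists(path)) {
    path <- file.path(builtin_source_dir(), paste0(source, ".yaml"))
    if (!file.exists(path))
      bc_config_error(sprintf(
        "unknown source model '%s' (built-ins: %s); pass a YAML file path to use a custom model",
        source, paste(list_source_models(), collapse = ", ")))
  }
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) bc_config_error(
                    sprintf("cannot parse source configuration '%s': %s",
                            path, conditionMessage(e))))
  for (f in c("name", "active_length_cm", "dose_rate_constant",
              "half_life_days", "radial", "anisotropy"))
    if (is.null(doc[[f]]))
      bc_config_error(sprintf("source configuration '%s' is missing field '%s'", path, f))
  source_spec(
    name = doc$name,
    active_length_cm = doc$active_length_cm,
    dose_rate_constant = doc$dose_rate_constant,
    half_life_days = doc$half_life_days,
    radial = doc$radial,
    anisotropy = doc$anisotropy,
    delta_g_percent = if (is.null(doc$delta_g_percent)) NA_real_ else doc$delta_g_percent,
    delta_F_percent = if (is.null(doc$delta_F_percent)) NA_real_ else doc$delta_F_percent)
}
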