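# Fixture source models built in code.

builtin_spec <- function() load_source_spec("GammaMedPlus-Ir192")

# Degenerate model with F == 1 everywhere and g_L == 1 at every radius:
# isolates the geometry factor in engine tests.
flat_spec <- function(L = 0.35, Lambda = 1.118, half_life = 73.83) {
  source_spec(
    name = "flat-test-source",
    active_length_cm = L,
    dose_rate_constant = Lambda,
    half_life_days = half_life,
    radial = c(h = 1, i = 0, j = 0, k = 0),
    anisotropy = list(k = c(0, 0, 0, 1), a = c(0, 0, 0, 0),
                      b = c(0, 0, 0, 0), e = c(0, 0, 0, 0),
                      a_prime = c(0, 0, 0, 0), b_prime = c(0, 0, 0, 0),
                      e_prime = c(0, 0, 0, 0)))
}

axial_dwell <- function(center = c(0, 0, 0), t = 3600, index = 1L) {
  dwell_position(index, dwell_geometry(center, c(0, 0, 1)), t)
}

# a small self-consistent plan written/read by several IO tests
tiny_plan <- function(tps_dose = c(100, 200)) {
  brachy_plan(
    plan_id = "tiny",
    source_model_name = "GammaMedPlus-Ir192",
    calibration = kerma_calibration(40700, "2026-09-01", "2026-09-10"),
    dwells = list(
      dwell_position(1L, dwell_geometry(c(0, 0, 0), c(0, 0, 1)), 12.5, "tandem"),
      dwell_position(2L, dwell_geometry(c(0, 0, 0.5), c(0, 0, 1)), 31.25, "tandem")),
    points = list(
      verification_point("point A left", c(-2, 0, 2), tps_dose[1]),
      verification_point("bladder", c(0, 2, 1), tps_dose[2], dose_source = "target")))
}
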