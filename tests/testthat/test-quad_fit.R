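# The grid search: exact recovery, noise behaviour, degeneracy handling,
# window sliding, determinism and refinement monotonicity.

coef_of <- function(f) c(f$curve$r, f$curve$p, f$curve$t, f$delta)

test_that("fit_quadruple recovers exact helical quadruples at the grid center", {
  set.seed(101)
  hc <- helical_curve(2.3, 1.5, 1.7453, random_rotation(), runif(3, -10, 10))
  quad <- helix_points(hc, hc$t * 0:3)
  fit <- fit_quadruple(quad)
  expect_lt(fit$delta, 1e-6)
  expect_equal(fit$curve$r, 2.3, tolerance = 1e-9)
  expect_equal(fit$curve$p, 1.5, tolerance = 1e-9)
  expect_equal(fit$curve$t, 1.7453, tolerance = 1e-9)
  # delta is the RMS of the per-atom closest-point distances
  expect_equal(fit$delta, sqrt(mean(fit$atom_dists^2)), tolerance = 1e-9)
  # atom phases run monotonically along the chain
  expect_true(all(diff(fit$atom_phases) > 0))
})

test_that("moderate noise keeps delta bounded and parameters near truth", {
  set.seed(102)
  hc <- helical_curve(2.3, 1.5, 1.7453)
  quad <- helix_points(hc, hc$t * 0:3) + matrix(rnorm(12, 0, 0.05), 4, 3)
  fit <- fit_quadruple(quad)
  expect_gt(fit$delta, 0)
  expect_lt(fit$delta, 3 * 0.05)
  expect_lt(abs(fit$curve$r - 2.3), 0.25)
})

test_that("degenerate quadruples error out", {
  expect_error(fit_quadruple(cbind(3.8 * 0:3, 0, 0)), "degenerate")
})

test_that("fit_trace slides one window per quadruple and stride3 decimates", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 12,
                                      seed = 9))
  fit <- helixfit(tr)
  cf <- coef(fit)
  expect_equal(nrow(cf), 9L)
  expect_true(all(cf[, "delta"] <= 1e-6))
  expect_lt(max(cf[, "r"]) - min(cf[, "r"]), 1e-9)
  expect_lt(max(cf[, "t"]) - min(cf[, "t"]), 1e-9)

  # stride-3 working list of a 12-atom trace has 4 atoms: exactly one window
  dna <- generate_fixture(fixture_spec("ideal_bdna_strand", n_atoms = 12,
                                       seed = 9))
  f3 <- helixfit(dna, stride3 = TRUE)
  expect_equal(nrow(coef(f3)), 1L)
  # the decimated turn angle triples the per-nucleotide twist
  expect_equal(abs(unname(coef(f3)[1, "t"])), 3 * 36 * pi / 180,
               tolerance = 0.05)

  short <- expect_warning(helixfit(tr$xyz[1:3, , drop = FALSE]),
                          "too short")
  expect_length(helixfit:::good_fits(short), 0L)
})

test_that("a far-displaced atom degrades only the windows containing it", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 12,
                                      seed = 10))
  xyz <- tr$xyz
  xyz[6, ] <- xyz[6, ] + c(1, -0.7, 0.5)
  fit <- helixfit(helix_trace(xyz))
  cf <- coef(fit)
  touches <- cf[, "window"] %in% 3:6   # windows covering atom 6
  expect_true(all(cf[touches, "delta"] > 0.05))
  expect_true(all(cf[!touches, "delta"] <= 1e-6))
})

test_that("fitting is deterministic and rigid-motion invariant", {
  set.seed(103)
  hc <- helical_curve(3.1, 2.2, 1.1)
  quad <- helix_points(hc, hc$t * 0:3) + matrix(rnorm(12, 0, 0.04), 4, 3)
  f1 <- fit_quadruple(quad)
  f2 <- fit_quadruple(quad)
  expect_identical(coef_of(f1), coef_of(f2))   # bit-identical rerun

  for (i in 1:5) {
    Q <- random_rotation(); s <- runif(3, -10, 10)
    fm <- fit_quadruple(rigid(quad, Q, s))
    expect_equal(fm$curve$r, f1$curve$r, tolerance = 1e-6)
    expect_equal(fm$curve$p, f1$curve$p, tolerance = 1e-6)
    expect_equal(fm$curve$t, f1$curve$t, tolerance = 1e-6)
    expect_equal(fm$delta, f1$delta, tolerance = 1e-6)
  }
})

test_that("halving the grid step never increases the fitted delta", {
  set.seed(104)
  hc <- helical_curve(2.5, 1.3, 1.6)
  quad <- helix_points(hc, hc$t * 0:3) + matrix(rnorm(12, 0, 0.08), 4, 3)
  d_coarse <- fit_quadruple(quad, fit_config(step = 0.02))$delta
  d_fine <- fit_quadruple(quad, fit_config(step = 0.01))$delta
  d_finer <- fit_quadruple(quad, fit_config(step = 0.005))$delta
  expect_lte(d_fine, d_coarse + 1e-12)
  expect_lte(d_finer, d_fine + 1e-12)
})

test_that("fit_config validates its grid", {
  expect_error(fit_config(step = 0), "step")
  expect_error(fit_config(delta_r = 0.01, step = 0.2), "step must be")
})

test_that("fits roundtrip through JSON lines", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 6,
                                      seed = 12))
  fit <- helixfit(tr)
  f <- tempfile(fileext = ".jsonl")
  write_fits_jsonl(fit, f)
  back <- read_fits_jsonl(f)
  expect_length(back, 3L)
  expect_equal(back[[1]]$curve$r, unname(coef(fit)[1, "r"]))
  expect_equal(back[[2]]$delta, unname(coef(fit)[2, "delta"]))
  expect_equal(back[[1]]$curve$rotation,
               helixfit:::good_fits(fit)[[1]]$curve$rotation)
})
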