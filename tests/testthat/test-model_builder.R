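# The averaging that merges window curves into one C0-continuous model
# curve, and the helix center polyline.

test_that("curve segments start and end at the atoms' closest curve points", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 6,
                                      seed = 401))
  fit <- helixfit:::good_fits(helixfit(tr))[[1]]
  seg <- curve_segment(fit, fit$atom_phases[1], fit$atom_phases[2], m = 2L)
  expect_equal(nrow(seg), 2L)
  expect_lt(sqrt(sum((seg[1, ] - fit$atoms[1, ])^2)), 1e-6)
  expect_lt(sqrt(sum((seg[2, ] - fit$atoms[2, ])^2)), 1e-6)

  # interior samples lie on the fitted curve
  seg3 <- curve_segment(fit, fit$atom_phases[1], fit$atom_phases[2], m = 3L)
  cp <- closest_point(fit$curve, seg3[2, ],
                      fit$atom_phases[1:2] + c(-0.5, 0.5))
  expect_lt(cp$distance, 1e-9)

  expect_error(curve_segment(fit, 1, 1, m = 4L), "from_phase")
})

test_that("densely sampled segment length approaches the helical arc length", {
  r <- 2.3; p <- 1.5; t <- 1.7453
  tr <- helix_trace(helix_points(helical_curve(r, p, t), t * (0:5)))
  fit <- helixfit:::good_fits(helixfit(tr))[[1]]
  seg <- curve_segment(fit, fit$atom_phases[1], fit$atom_phases[2], m = 400L)
  arclen <- sum(sqrt(rowSums(diff(seg)^2)))
  expect_equal(arclen, sqrt(p^2 + (r * t)^2), tolerance = 1e-4)
})

test_that("averaging identical window curves reproduces the generating curve", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 10,
                                      seed = 402))
  fit <- helixfit(tr)
  model <- build_model(fit, m = 16L)
  expect_equal(model$contributors, c(1L, 2L, 3L, 3L, 3L, 3L, 3L, 2L, 1L))
  cv <- attr(tr, "curve")
  samp <- model_samples(model)
  dev <- vapply(seq_len(nrow(samp)), function(i)
    closest_point(cv, samp[i, ], c(-2 * pi, 11 * abs(cv$t) + 2 * pi))$distance,
    numeric(1))
  expect_lt(max(dev), 1e-6)
})

test_that("adjacent segments share their boundary samples exactly", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 9, seed = 403))
  model <- build_model(helixfit(tr), m = 8L)
  for (k in seq_len(length(model$segments) - 1L)) {
    expect_identical(model$segments[[k]][8L, ],
                     model$segments[[k + 1L]][1L, ])
  }
})

test_that("a 5-atom trace averages its 4 segments from (1, 2, 2, 1) curves", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 5, seed = 404))
  model <- build_model(helixfit(tr))
  expect_equal(model$contributors, c(1L, 2L, 2L, 1L))
})

test_that("a degenerate window drops one contributor from its segments", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 10,
                                      seed = 405, random_placement = FALSE))
  fit <- helixfit(tr)
  fit$fits[4] <- list(NULL)   # simulate a degeneracy gap at window 4
  model <- build_model(fit)
  expect_equal(model$contributors, c(1L, 2L, 3L, 2L, 2L, 2L, 3L, 2L, 1L))
})

test_that("model curvature is constant on exact helical input", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 10,
                                      seed = 406))
  model <- build_model(helixfit(tr), m = 24L)
  k <- helixfit:::.discrete_curvature(model_samples(model))
  expect_lt((max(k) - min(k)) / stats::median(k), 1e-6)
})

test_that("atoms stay close to the averaged model on noisy fixtures", {
  for (s in 1:5) {
    tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 8, seed = s))
    fit <- helixfit(tr)
    model <- build_model(fit)
    d <- detachment(tr, model, thickness = Inf)$distance
    expect_lte(max(d), 2 * max(coef(fit)[, "delta"]))
  }
})

test_that("the center polyline is straight for an ideal helix", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 12,
                                      seed = 407))
  pl <- center_polyline(helixfit(tr))
  expect_equal(nrow(pl$vertices), 9L)
  expect_true(all(pl$bend_angles <= 1e-4))
})

test_that("a 30-degree axis kink appears as a matching bend at the junction", {
  tr <- generate_fixture(fixture_spec("kinked_helix", n_atoms = 16,
                                      kink_angle = 30 * pi / 180, seed = 408))
  fit <- helixfit(tr)
  pl <- center_polyline(fit, max_delta = 0.08)
  bend_deg <- pl$bend_angles * 180 / pi
  expect_lt(abs(max(bend_deg) - 30), 5)
  # the junction sits between the two ideal arms
  j <- which.max(bend_deg) + 1L
  expect_gt(j, 3L)
  expect_lt(j, nrow(pl$vertices) - 2L)
})

test_that("a single fit yields a one-vertex polyline without bends", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 4, seed = 409))
  pl <- center_polyline(helixfit(tr))
  expect_equal(nrow(pl$vertices), 1L)
  expect_length(pl$bend_angles, 0L)
})

test_that("model curves export to JSON and pseudo-atom PDB", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 6, seed = 410))
  model <- build_model(helixfit(tr), m = 4L)
  fj <- tempfile(fileext = ".json")
  write_model_json(model, fj)
  back <- jsonlite::fromJSON(fj, simplifyVector = FALSE)
  expect_equal(back$m, 4L)
  expect_length(back$segments, 5L)
  fp <- tempfile(fileext = ".pdb")
  write_model_pdb(model, fp)
  expect_true(any(grepl("^HETATM", readLines(fp))))
})
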