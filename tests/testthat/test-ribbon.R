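# Ribbon meshes, the detachment diagnostic, the choppiness metric and the
# Hermite comparison baseline.

test_that("ribbon meshes have the advertised structure", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 8, seed = 501))
  fit <- helixfit(tr)
  model <- build_model(fit, m = 6L)
  sc <- helix_scores(fit)
  mesh <- build_ribbon(model, fit, sc, width = 2.0, thickness = 0.5)
  ns <- nrow(model_samples(model))
  expect_equal(nrow(mesh$vertices), 8L * ns)
  expect_equal(nrow(mesh$normals), 8L * ns)
  expect_equal(nrow(mesh$colors), 8L * ns)
  # 8 triangles per inter-sample quad band plus 2 per end cap
  expect_equal(nrow(mesh$faces), 8L * (ns - 1L) + 4L)
  expect_true(all(mesh$faces >= 1L & mesh$faces <= 8L * ns))
  # unit normals
  expect_equal(unname(sqrt(rowSums(mesh$normals^2))), rep(1, 8L * ns),
               tolerance = 1e-9)
  # colors are valid bytes
  expect_true(all(mesh$colors >= 0L & mesh$colors <= 255L))
  expect_error(build_ribbon(model, fit, sc, width = 0.4, thickness = 0.5))
})

test_that("ribbon cross-sections honor width and thickness", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 8,
                                      seed = 502))
  fit <- helixfit(tr)
  model <- build_model(fit, m = 4L)
  mesh <- build_ribbon(model, fit, NULL, width = 2.0, thickness = 0.5)
  # vertices 1 (+u+b) and 2 (-u+b) of a cross-section are width apart;
  # vertices 1 (+u+b) and 3 (+u-b) are thickness apart
  v <- mesh$vertices
  expect_equal(sqrt(sum((v[1, ] - v[2, ])^2)), 2.0, tolerance = 1e-9)
  expect_equal(sqrt(sum((v[1, ] - v[3, ])^2)), 0.5, tolerance = 1e-9)
  # every sample center sits within width/2 of the model curve samples
  samp <- model_samples(model)
  centers <- (v[seq(1, nrow(v), by = 8L), , drop = FALSE] +
                v[seq(4, nrow(v), by = 8L), , drop = FALSE]) / 2
  expect_equal(unname(centers), unname(samp), tolerance = 1e-9)
})

test_that("score colors map onto ribbon vertices by window bin", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 8, seed = 503))
  fit <- helixfit(tr)
  model <- build_model(fit, m = 4L)
  sc <- helix_scores(fit)
  sc$bin[] <- "red"                    # force a visible non-default bin
  mesh <- build_ribbon(model, fit, sc)
  red <- as.integer(grDevices::col2rgb(score_bin_colors()[["red"]]))
  expect_true(all(mesh$colors[-(1:8), 1] == red[1]))
  # NULL scores (DNA) give an all-green ribbon
  g <- build_ribbon(model, fit, NULL)
  green <- as.integer(grDevices::col2rgb(score_bin_colors()[["green"]]))
  expect_true(all(g$colors[, 2] == green[2]))
})

test_that("detachment flags a pulled atom and only that atom", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 10,
                                      seed = 504))
  model <- build_model(helixfit(tr))
  det0 <- detachment(tr, model, thickness = 0.5)
  expect_false(any(det0$detached))
  expect_lt(max(det0$distance), 1e-6)

  xyz <- tr$xyz
  xyz[5, ] <- xyz[5, ] + c(0.6, 0, 0)
  det1 <- detachment(xyz, model, thickness = 0.5)
  expect_true(det1$detached[5])
  expect_equal(sum(det1$detached), 1L)
  cl <- attr(det1, "closest")
  expect_equal(dim(cl), c(10L, 3L))
  expect_equal(sqrt(rowSums((xyz - cl)^2)), det1$distance, tolerance = 1e-9)
})

test_that("choppiness is near zero for the helical model, large for Hermite", {
  tr <- generate_fixture(fixture_spec("ideal_protein_helix", n_atoms = 10,
                                      seed = 505))
  fit <- helixfit(tr)
  model <- build_model(fit, m = 16L)
  base <- hermite_baseline(tr, m = 16L)
  expect_lt(choppiness(model), 1e-8)
  expect_gt(choppiness(base), 1e-3)
})

test_that("the Hermite baseline interpolates every guide atom", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 7, seed = 506))
  base <- hermite_baseline(tr, m = 8L)
  expect_s3_class(base, "model_curve")
  expect_length(base$segments, 6L)
  for (i in 1:6) {
    expect_equal(base$segments[[i]][1L, ], unname(tr$xyz[i, ]),
                 tolerance = 1e-9)
    expect_equal(base$segments[[i]][8L, ], unname(tr$xyz[i + 1L, ]),
                 tolerance = 1e-9)
  }
  # baseline detachment is 0 by construction (it passes through the atoms)
  expect_lt(max(detachment(tr, base, thickness = Inf)$distance), 1e-9)
})

test_that("mesh writers emit well-formed OBJ and PLY text", {
  tr <- generate_fixture(fixture_spec("noisy_helix", n_atoms = 6, seed = 507))
  fit <- helixfit(tr)
  mesh <- build_ribbon(build_model(fit, m = 3L), fit, helix_scores(fit))

  fo <- tempfile(fileext = ".obj")
  write_obj(mesh, fo)
  lo <- readLines(fo)
  expect_equal(sum(grepl("^v ", lo)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^vn ", lo)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", lo)), nrow(mesh$faces))

  fp <- tempfile(fileext = ".ply")
  write_ply(mesh, fp)
  lp <- readLines(fp)
  expect_equal(lp[1], "ply")
  expect_true(sprintf("element vertex %d", nrow(mesh$vertices)) %in% lp)
  expect_true(sprintf("element face %d", nrow(mesh$faces)) %in% lp)
  hdr <- which(lp == "end_header")
  expect_length(lp, hdr + nrow(mesh$vertices) + nrow(mesh$faces))

  # writers are bit-stable
  fo2 <- tempfile(fileext = ".obj")
  write_obj(mesh, fo2)
  expect_identical(readLines(fo2), lo)
})
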