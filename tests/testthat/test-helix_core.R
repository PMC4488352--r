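# Geometry primitives: curve evaluation, analytic seeds, turn angle,
# Kabsch superposition and closest-point queries.

test_that("helix_points follows the curve parameterisation exactly", {
  # planar circle case: z drops out when p = 0-ish rise with unit scaling
  hc <- helical_curve(1, 1e-12, pi / 2)
  pts <- helix_points(hc, c(0, pi / 2))
  expect_equal(pts[1, ], c(0, 1, 0), tolerance = 1e-9)
  expect_equal(pts[2, ], c(1, 0, 0), tolerance = 1e-9)

  # chord-length identity between consecutive residues
  r <- 2.3; p <- 1.5; t <- 1.7453
  hc <- helical_curve(r, p, t)
  pts <- helix_points(hc, c(0, t))
  chord <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  expect_equal(chord, sqrt(p^2 + 4 * r^2 * sin(t / 2)^2), tolerance = 1e-12)
})

test_that("helix_points is equivariant under rigid motions of the placement", {
  set.seed(11)
  for (i in 1:5) {
    hc <- random_curve()
    Q <- random_rotation(); s <- runif(3, -5, 5)
    moved <- helical_curve(hc$r, hc$p, hc$t, Q %*% hc$rotation,
                           as.numeric(Q %*% hc$origin + s))
    tau <- runif(4, -5, 5)
    expect_equal(helix_points(moved, tau),
                 rigid(helix_points(hc, tau), Q, s), tolerance = 1e-9)
  }
})

test_that("helical_curve validates its placement", {
  expect_error(helical_curve(-1, 1.5, 1.7), "r > 0")
  expect_error(helical_curve(2.3, 1.5, 4), "turn angle")
  expect_error(helical_curve(2.3, 1.5, 1.7, rotation = diag(3) * 2),
               "proper orthogonal")
  refl <- diag(c(1, 1, -1))
  expect_error(helical_curve(2.3, 1.5, 1.7, rotation = refl),
               "proper orthogonal")
})

test_that("seed_params recovers generating parameters from exact quadruples", {
  set.seed(21)
  for (i in 1:20) {
    hc <- random_curve()
    quad <- helix_points(hc, hc$t * 0:3)
    sp <- seed_params(quad)
    expect_equal(sp$r, hc$r, tolerance = 1e-9)
    expect_equal(sp$p, hc$p, tolerance = 1e-9)
    expect_equal(sp$t, hc$t, tolerance = 1e-9)
  }
})

test_that("seed_params is rigid-motion invariant and sign-aware", {
  set.seed(31)
  hc <- helical_curve(2.3, 1.5, 1.7453)
  quad <- helix_points(hc, hc$t * 0:3)
  sp0 <- seed_params(quad)
  Q <- random_rotation(); s <- runif(3, -10, 10)
  sp1 <- seed_params(rigid(quad, Q, s))
  expect_equal(sp1$r, sp0$r, tolerance = 1e-9)
  expect_equal(sp1$p, sp0$p, tolerance = 1e-9)
  expect_equal(sp1$t, sp0$t, tolerance = 1e-9)

  # left-handed generator: recovered t is negative with the same magnitude
  hcl <- helical_curve(2.3, 1.5, -1.7453)
  spl <- seed_params(helix_points(hcl, hcl$t * 0:3))
  expect_lt(spl$t, 0)
  expect_equal(abs(spl$t), 1.7453, tolerance = 1e-9)
})

test_that("seed_params rejects degenerate quadruples", {
  line <- cbind(3.8 * 0:3, 0, 0)
  expect_error(seed_params(line), "degenerate")
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))
  expect_error(seed_params(dup), "degenerate")
  # nearly straight: turn angle under the angular floor
  hc <- helical_curve(50, 0.5, 0.01)
  expect_error(seed_params(helix_points(hc, hc$t * 0:3)), "angular floor")
})

test_that("turn_angle inverts the chord-length identity", {
  expect_equal(turn_angle(2 * 2.3, 2.3, 0), pi)
  # chord computed from known (r, p, t), then inverted
  r <- 2.3; p <- 1.5; t <- 1.7453
  d <- sqrt(p^2 + 4 * r^2 * sin(t / 2)^2)
  expect_equal(d, 3.830, tolerance = 1e-3)
  expect_equal(turn_angle(d, r, p), t, tolerance = 1e-12)
  expect_error(turn_angle(1.0, 2.3, 1.5), "infeasible pitch")
  expect_error(turn_angle(10, 2.3, 1.5), "infeasible radius")
})

test_that("superpose satisfies the Kabsch contract", {
  set.seed(41)
  pts <- matrix(rnorm(12, sd = 3), 4, 3)

  # identity case
  s0 <- superpose(pts, pts)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)

  # recovery of a known rigid motion, proper rotation guaranteed
  for (i in 1:10) {
    Q <- random_rotation(); sh <- runif(3, -10, 10)
    out <- superpose(pts, rigid(pts, Q, sh))
    expect_equal(out$rotation, Q, tolerance = 1e-9)
    expect_equal(out$translation, sh, tolerance = 1e-9)
    expect_equal(out$rmsd, 0, tolerance = 1e-9)
    expect_equal(det(out$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(out$rotation), diag(3), tolerance = 1e-9)
  }

  # mirrored chiral set: rotation stays proper and cannot reach rmsd 0
  mirror <- pts %*% diag(c(1, 1, -1))
  om <- superpose(pts, mirror)
  expect_equal(det(om$rotation), 1, tolerance = 1e-9)
  expect_gt(om$rmsd, 0.1)

  # rmsd invariant under a common relabeling of both sets
  perm <- c(3, 1, 4, 2)
  Q <- random_rotation(); sh <- c(1, -2, 3)
  noisy <- rigid(pts, Q, sh) + matrix(rnorm(12, sd = 0.1), 4, 3)
  expect_equal(superpose(pts, noisy)$rmsd,
               superpose(pts[perm, ], noisy[perm, ])$rmsd,
               tolerance = 1e-9)
})

test_that("superpose agrees with an independent reference implementation", {
  set.seed(51)
  a <- matrix(rnorm(18, sd = 3), 6, 3)
  b <- rigid(a, random_rotation(), c(2, -1, 4)) +
    matrix(rnorm(18, sd = 0.3), 6, 3)
  ours <- superpose(a, b)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("closest_point finds on-curve and axis queries exactly", {
  hc <- helical_curve(2.3, 1.5, 1.7453, rotation = random_rotation(),
                      origin = c(1, 2, 3))
  tau0 <- 0.73
  q <- helix_points(hc, tau0)[1, ]
  cp <- closest_point(hc, q, c(-pi, pi + 3 * 1.7453))
  expect_equal(cp$distance, 0, tolerance = 1e-7)
  expect_equal(cp$phase, tau0, tolerance = 1e-4)

  # axis point at curve height 0: all phases at height 0 are r away
  hc0 <- helical_curve(2.3, 1e-9, 1.7453)
  cp0 <- closest_point(hc0, c(0, 0, 0), c(-pi, pi))
  expect_equal(cp0$distance, 2.3, tolerance = 1e-6)

  expect_error(closest_point(hc, q, c(1, 1)), "empty")
})

test_that("closest_point matches the brute-force oracle and dominates samples", {
  set.seed(61)
  for (i in 1:25) {
    hc <- random_curve()
    q <- helix_points(hc, runif(1, 0, 3 * abs(hc$t)))[1, ] + rnorm(3, sd = 2)
    win <- c(-pi, 3 * abs(hc$t) + pi)
    cp <- closest_point(hc, q, win)
    bf <- helixfit:::closest_point_brute(hc, q, win, n = 2e5)
    expect_lte(cp$distance, bf$distance + 1e-9)   # oracle dominance
    expect_equal(cp$distance, bf$distance, tolerance = 1e-5)
  }
})

test_that("helical curves roundtrip through JSON", {
  set.seed(71)
  hc <- random_curve()
  hc2 <- curve_from_json(curve_to_json(hc))
  expect_equal(hc2$r, hc$r)
  expect_equal(hc2$rotation, hc$rotation)
  expect_equal(hc2$origin, hc$origin)
})
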