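test_that("mirror templates reconstruct the ramp example by hand", {
  ramp <- matrix(rep(0:4, each = 5), 5, 5)
  tq <- extract_templates(ramp, 3, 3, 5)
  expect_equal(tq$T_L[1, ], c(0, 1, 2, 1, 0))
  expect_equal(tq$T_R[1, ], c(4, 3, 2, 3, 4))
  # rows of the vertical-split templates are constant down the columns
  expect_true(all(apply(tq$T_L, 2, function(col) length(unique(col)) == 1)))
  # transposed ramp exercises the horizontal split the same way
  tq2 <- extract_templates(t(ramp), 3, 3, 5)
  expect_equal(tq2$T_T[, 1], c(0, 1, 2, 1, 0))
  expect_equal(tq2$T_B[, 1], c(4, 3, 2, 3, 4))
})

test_that("templates at the center of a symmetric image coincide", {
  sp <- particle_spec("rings", radius = 12, center = c(33, 31))
  px <- render_particle(sp, 64, 64, background = 0.5)$pixels
  tq <- extract_templates(px, 33, 31, 29)
  expect_equal(tq$T_L, tq$T_R)
  expect_equal(tq$T_T, tq$T_B)
  # each template is itself exactly mirror symmetric about its central axis
  expect_equal(tq$T_L, tq$T_L[, 29:1])
  expect_equal(tq$T_T, tq$T_T[29:1, ])
})

test_that("template extraction validates its inputs", {
  px <- matrix(runif(100), 10, 10)
  expect_error(extract_templates(px, 5, 5, 4), "odd")
  expect_error(extract_templates(px, 2, 5, 7), "exits the image")
  tq <- extract_templates(matrix(1, 9, 9), 5, 5, 5)
  expect_true(all(tq$T_L == 1) && all(tq$T_B == 1))
})

test_that("correlation maps match a brute-force per-candidate oracle", {
  set.seed(99)
  for (rep in 1:5) {
    px <- matrix(runif(15 * 15), 15, 15)
    maps <- correlation_maps(px, c(8, 8), n = 5, half_width = 2)
    oracle <- brute_force_maps(px, 6:10, 6:10, 5)
    expect_lt(max(abs(maps$corr_x - oracle$corr_x)), 1e-12)
    expect_lt(max(abs(maps$corr_y - oracle$corr_y)), 1e-12)
  }
})

test_that("correlation maps are bounded and peak at a true symmetry center", {
  sp <- particle_spec("rings", radius = 10, center = c(32, 32))
  sc <- render_particle(sp, 64, 64, background = 0.5)
  maps <- correlation_maps(sc, c(33, 31), n = 25, half_width = 3)
  expect_true(all(maps$corr_x >= -1 & maps$corr_x <= 1))
  expect_true(all(maps$corr_y >= -1 & maps$corr_y <= 1))
  at_truth <- which(maps$xs == 32)
  expect_equal(maps$corr_x[which(maps$ys == 32), at_truth], 1)
  expect_equal(max(maps$corr_x), 1)
})

test_that("perfect anticorrelation and degenerate templates are handled", {
  a <- matrix(runif(49), 7, 7)
  b <- -(a - mean(a)) + mean(a)
  expect_equal(csym:::template_correlation(a, b), -1)
  expect_equal(csym:::template_correlation(a, matrix(0.3, 7, 7)), 0)
  # flat image: every candidate degenerate, correlation 0 and flagged
  maps <- correlation_maps(matrix(1, 21, 21), c(11, 11), n = 7,
                           half_width = 2)
  expect_true(all(maps$corr_x == 0))
  expect_true(all(maps$degenerate))
})

test_that("candidates whose ROI exits the image are clamped away", {
  px <- matrix(runif(21 * 21), 21, 21)
  maps <- correlation_maps(px, c(4, 11), n = 7, half_width = 3)
  expect_equal(min(maps$xs), 4L)  # x = 1..3 would need pixels off-image
  # only the exact center accommodates a 21-px ROI; nothing fits a 23-px one
  solo <- correlation_maps(px, c(11, 11), n = 21, half_width = 3)
  expect_equal(dim(solo$corr_x), c(1L, 1L))
  expect_error(correlation_maps(px, c(11, 11), n = 23, half_width = 3),
               "no candidate ROI fits")
})

test_that("symmetry profiles are the orthogonal means of the maps", {
  set.seed(4)
  maps <- structure(list(corr_x = matrix(runif(25, -1, 1), 5, 5),
                         corr_y = matrix(runif(25, -1, 1), 5, 5),
                         xs = 1:5, ys = 1:5,
                         degenerate = matrix(FALSE, 5, 5)),
                    class = "csym_maps")
  prof <- symmetry_profiles(maps)
  expect_equal(prof$sym_x, colMeans(maps$corr_x))
  expect_equal(prof$sym_y, rowMeans(maps$corr_y))
  maps$corr_x[] <- 0.37
  expect_equal(unname(symmetry_profiles(maps)$sym_x), rep(0.37, 5))
})

test_that("Hermite interpolation passes through knots and reproduces lines", {
  v <- c(0.2, 0.9, 0.4, 0.7, 0.1)
  crv <- hermite_interpolate(v, 1:5, step = 0.01)
  at_knots <- crv$y[match(1:5, crv$x)]
  expect_equal(at_knots, v)
  lin <- hermite_interpolate(c(0, 1, 2, 3), step = 0.01)
  expect_lt(max(abs(lin$y - (lin$x - 1))), 1e-12)
  expect_error(hermite_interpolate(c(1, 2)), "at least 3")
  # C1 continuity: secant slopes straddling each interior knot agree to
  # within the curvature of one dense step
  d <- diff(crv$y) / 0.01
  for (k in 2:4) {
    i <- match(k, crv$x)
    expect_lt(abs(d[i] - d[i - 1]), 0.05)
  }
})

test_that("tent profile interpolates to a maximum at the middle knot", {
  crv <- hermite_interpolate(c(0, 1, 0), 1:3, step = 0.001)
  expect_equal(max(crv$y), 1)
  expect_equal(crv$x[which.max(crv$y)], 2)
})

test_that("monotone slope limiting matches the Fritsch-Carlson reference", {
  v <- c(0, 0.1, 0.9, 1, 1)
  crv <- hermite_interpolate(v, 1:5, step = 0.01, monotone = TRUE)
  f <- splinefun(1:5, v, method = "monoH.FC")
  expect_equal(crv$y, f(crv$x))
  expect_true(all(diff(crv$y) >= -1e-12))
})

test_that("peak refinement recovers an exact quadratic", {
  xs <- 0:4
  prof <- -(xs - 1.7)^2 + 3
  for (hermite in c(TRUE, FALSE)) {
    r <- peak_refine(prof, xs, hermite = hermite)
    expect_equal(r$center, 1.7, tolerance = 1e-9)
    expect_equal(r$q[1], -1, tolerance = 1e-9)
    expect_true(r$converged)
  }
})

test_that("peak refinement is exact on symmetric profiles and flags edge peaks", {
  r <- peak_refine(c(0.2, 0.8, 1, 0.8, 0.2), 1:5)
  expect_equal(r$center, 3, tolerance = 1e-12)
  edge <- peak_refine(c(0.1, 0.2, 0.4, 0.7, 0.9), 1:5)
  expect_false(edge$converged)
  flat <- peak_refine(rep(0.5, 7), 1:7)
  expect_false(flat$converged)  # q1 = 0: no maximum
})

test_that("C-Sym recovers noiseless symmetric centers to sub-millipixel", {
  for (pat in c("rings", "airy", "gaussian")) {
    sp <- particle_spec(pat, radius = 10, center = c(64, 64))
    sc <- render_particle(sp, 128, 128, background = 0.3)
    loc <- locate_csym(sc, guess = c(65, 63))
    expect_lt(abs(loc$x - 64), 1e-3)
    expect_lt(abs(loc$y - 64), 1e-3)
    expect_true(loc$converged)
    expect_gt(loc$peak_corr_x, 0.999)
  }
})

test_that("C-Sym locates off-grid centers within the sampling limit", {
  for (pat in c("airy", "gaussian", "spot")) {
    sp <- particle_spec(pat, radius = 10, center = c(63.58, 64.23))
    sc <- render_particle(sp, 128, 128, background = 0.3)
    loc <- locate_csym(sc, guess = c(64, 64))
    err <- sqrt((loc$x - 63.58)^2 + (loc$y - 64.23)^2)
    expect_lt(err, 0.05)
  }
  # the sharp-rimmed multi-ring bead pattern has pattern structure near the
  # pixel scale, so its discrete-symmetry sampling floor is higher
  sp <- particle_spec("rings", radius = 10, center = c(63.58, 64.23))
  sc <- render_particle(sp, 128, 128, background = 0.3)
  loc <- locate_csym(sc, guess = c(64, 64))
  expect_lt(sqrt((loc$x - 63.58)^2 + (loc$y - 64.23)^2), 0.1)
})

test_that("C-Sym is exactly equivariant under integer translation", {
  sp1 <- particle_spec("rings", radius = 10, center = c(50.3, 60.7))
  sp2 <- particle_spec("rings", radius = 10, center = c(50.3 + 7, 60.7 - 5))
  sc1 <- render_particle(sp1, 128, 128, background = 0.4)
  sc2 <- render_particle(sp2, 128, 128, background = 0.4)
  l1 <- locate_csym(sc1, guess = c(51, 60))
  l2 <- locate_csym(sc2, guess = c(51 + 7, 60 - 5))
  expect_equal(l2$x - l1$x, 7, tolerance = 1e-6)
  expect_equal(l2$y - l1$y, -5, tolerance = 1e-6)
})

test_that("transposing the image swaps the located coordinates exactly", {
  tr <- make_trial(10, 2, seed = 31, width = 96, height = 96)
  l <- locate_csym(tr$pixels, guess = tr$initial_guess, roi_size = 25)
  lt <- locate_csym(t(tr$pixels), guess = rev(tr$initial_guess),
                    roi_size = 25)
  expect_identical(l$x, lt$y)
  expect_identical(l$y, lt$x)
})

test_that("the locate pipeline is deterministic and never silently NaN", {
  tr <- make_trial(10, 0.5, seed = 12, width = 96, height = 96)
  a <- locate_csym(tr)
  b <- locate_csym(tr)
  expect_identical(tidy(a), tidy(b))
  expect_true(is.finite(a$x) && is.finite(a$y))
  expect_error(locate_csym(tr$pixels), "guess")
  expect_error(locate_csym(tr$pixels, guess = c(48, 48)), "roi_size")
})

test_that("disabling Hermite interpolation still localizes, less finely", {
  sp <- particle_spec("rings", radius = 10, center = c(64.4, 63.8))
  sc <- render_particle(sp, 128, 128, background = 0.3)
  plain <- locate_csym(sc, guess = c(64, 64), hermite = FALSE)
  expect_true(plain$converged)
  expect_lt(sqrt((plain$x - 64.4)^2 + (plain$y - 63.8)^2), 0.5)
  expect_null(plain$curves$x)
})

test_that("ROI sizing follows the 1.2x-extent odd-integer policy", {
  sp <- particle_spec("rings", radius = 50, center = c(256, 256))
  expect_equal(csym:::default_roi_size(sp), 121L)
  sp10 <- particle_spec("rings", radius = 10, center = c(256, 256))
  expect_equal(csym:::default_roi_size(sp10), 25L)
  spg <- particle_spec("gaussian", radius = 10, center = c(256, 256))
  expect_equal(csym:::default_roi_size(spg), 49L)
})
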