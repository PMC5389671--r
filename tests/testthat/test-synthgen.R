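test_that("gaussian rendering matches the closed-form intensity model", {
  sp <- particle_spec("gaussian", radius = 10, center = c(256, 256),
                      amplitude = 0.5)
  sc <- render_particle(sp, 512, 512, background = 0.25)
  expect_equal(sc$pixels[256, 256], 0.75)
  expect_equal(sc$pixels[256, 266], 0.25 + 0.5 * exp(-1))
  expect_equal(sc$pixels[246, 256], 0.25 + 0.5 * exp(-1))
  # anisotropic stretch rescales the radial coordinate per axis
  sp2 <- particle_spec("gaussian", radius = 10, center = c(256, 256),
                       amplitude = 0.5, stretch = c(2, 1))
  sc2 <- render_particle(sp2, 512, 512, background = 0.25)
  expect_equal(sc2$pixels[256, 276], 0.25 + 0.5 * exp(-1))
})

test_that("on-grid particles are exactly mirror symmetric about their center", {
  for (pat in c("rings", "airy", "gaussian", "spot")) {
    sp <- particle_spec(pat, radius = 15, center = c(64, 64))
    px <- render_particle(sp, 128, 128, background = 0.4)$pixels
    expect_equal(max(abs(px[, 63:34] - px[, 65:94])), 0, info = pat)
    expect_equal(max(abs(px[63:34, ] - px[65:94, ])), 0, info = pat)
    # point reflection about the center leaves the image unchanged
    expect_equal(cor(as.vector(px[1:127, 1:127]),
                     as.vector(px[127:1, 127:1])), 1, info = pat)
  }
})

test_that("off-grid ringed particles have matching radial cuts on both axes", {
  sp <- particle_spec("airy", radius = 50, center = c(200.3, 310.7))
  px <- render_particle(sp, 512, 512, background = 0.4)$pixels
  offs <- seq(5, 45, by = 0.5)
  horiz <- approx(seq_len(512), px[311, ], xout = 200.3 + offs)$y
  vert <- approx(seq_len(512), px[, 200], xout = 310.7 + offs)$y
  # the two cuts sample the same radial profile; subpixel interpolation and
  # the 0.3/0.7 px offsets of the cut lines bound the agreement
  expect_lt(max(abs(horiz - vert)), 0.01)
})

test_that("renderer rejects invalid specs and frames", {
  expect_error(particle_spec("rings", radius = -1, center = c(10, 10)),
               "positive")
  expect_error(particle_spec("rings", radius = 5, center = c(10, 10),
                             amplitude = 1.5), "amplitude")
  sp <- particle_spec("rings", radius = 10, center = c(12, 12))
  expect_error(render_particle(sp, 30, 30), "at least 4 x radius")
  sp2 <- particle_spec("rings", radius = 10, center = c(3, 20))
  expect_error(render_particle(sp2, 64, 64), "margin")
})

test_that("noise level inverts the SNR definition exactly", {
  expect_equal(snr_sigma(1, 4), 0.05)
  expect_equal(snr_sigma(0.5, 0.1), 0.5 / 4.4)
  expect_error(snr_sigma(1, 0), "positive")
  expect_error(snr_sigma(0, 1), "constant")
})

test_that("added noise has the calibrated standard deviation", {
  sp <- particle_spec("gaussian", radius = 10, center = c(256, 256),
                      amplitude = 1)
  clean <- render_particle(sp, 512, 512, background = 0)
  rng <- range(clean$pixels)
  noisy <- add_noise_to_snr(clean, 4, seed = 11)
  sigma <- (rng[2] - rng[1]) / 20
  expect_equal(noisy$noise_sigma, sigma)
  emp <- sd(noisy$pixels - clean$pixels)
  expect_lt(abs(emp - sigma) / sigma, 0.03)
  expect_error(add_noise_to_snr(noisy, 4), "already")
})

test_that("measured SNR round-trips through noise injection", {
  sp <- particle_spec("rings", radius = 12, center = c(32, 32))
  clean <- render_particle(sp, 64, 64, background = 0.5)
  for (snr in c(0.1, 1, 37.5, 100)) {
    noisy <- add_noise_to_snr(clean, snr, seed = 5)
    expect_equal(measure_snr(noisy), snr, tolerance = 1e-12)
  }
  expect_error(measure_snr(clean), "no recorded noise")
})

test_that("randomized trials respect the generator contract", {
  for (seed in c(1, 17, 933)) {
    tr <- make_trial(10, 1, seed = seed, width = 64, height = 64, )
    expect_gte(tr$background, 0.25)
    expect_lte(tr$background, 0.75)
    expect_lte(max(abs(tr$initial_guess - tr$truth$center)), 2)
    expect_equal(tr$initial_guess, round(tr$initial_guess))
  }
})

test_that("identical seeds give bit-identical scenes, distinct seeds distinct truth", {
  a <- make_trial(10, 1, seed = 42, width = 64, height = 64)
  b <- make_trial(10, 1, seed = 42, width = 64, height = 64)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)
  centers <- vapply(1:100, function(s)
    make_trial(6, Inf, seed = s, width = 48, height = 48)$truth$center[["x"]],
    numeric(1))
  expect_equal(length(unique(centers)), 100L)
})

test_that("trial backgrounds are uniform on [0.25, 0.75]", {
  bgs <- vapply(1:1000, function(s)
    make_trial(6, Inf, seed = s, width = 48, height = 48)$background,
    numeric(1))
  ks <- suppressWarnings(ks.test(bgs, "punif", 0.25, 0.75))
  expect_gt(ks$p.value, 0.01)
})

test_that("pair scenes place two identical interfering particles", {
  pr <- make_pair_trial(20, 3, Inf, seed = 8)
  expect_equal(pr$truth$radius, pr$truth2$radius)
  expect_equal(pr$truth$amplitude, pr$truth2$amplitude)
  d <- sqrt(sum((pr$truth$center - pr$truth2$center)^2))
  expect_equal(d, 3 * rayleigh_limit(pr$truth))
  # noiseless: local intensity extremum nearest each truth is within 1 px
  for (ctr in list(pr$truth$center, pr$truth2$center)) {
    cx <- round(ctr[["x"]]); cy <- round(ctr[["y"]])
    win <- abs(pr$pixels[(cy - 5):(cy + 5), (cx - 5):(cx + 5)] -
                 pr$background)
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 6)), 1)
  }
  expect_error(make_pair_trial(150, 3, Inf, seed = 1), "outside the frame")
})

test_that("a pair at any separation is mirror symmetric about its bisector", {
  a <- render_particle(particle_spec("airy", 10, c(30, 40)), 80, 80, 0)$pixels
  b <- render_particle(particle_spec("airy", 10, c(40, 40)), 80, 80, 0)$pixels
  pair <- 0.5 + a + b
  expect_equal(max(abs(pair[, 34:15] - pair[, 36:55])), 0)
})

test_that("ground-truth tables carry the sidecar schema", {
  scenes <- lapply(1:3, function(s)
    make_trial(6, 2, seed = s, width = 48, height = 48))
  gt <- ground_truth_table(scenes, seeds = 1:3)
  expect_named(gt, c("trial_id", "pattern", "radius", "snr", "seed",
                     "truth_x", "truth_y", "guess_x", "guess_y",
                     "background", "sigma"))
  expect_equal(nrow(gt), 3L)
  expect_equal(gt$sigma[1], scenes[[1]]$noise_sigma)
})
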