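test_that("the FA-to-concentration map is monotone with the right limits", {
  expect_equal(kappa_from_fa(0), 0)
  fa <- seq(0, 0.95, by = 0.05)
  k <- kappa_from_fa(fa)
  expect_true(all(diff(k) > 0))
  expect_equal(kappa_from_fa(1, kappa_max = 500), 500)
})

test_that("orientation models pass fiber geometry through faithfully", {
  ph <- tiny_phantom()
  m <- orientation_model_from_fibers(ph$fibers, ph$fa_true)
  cross <- which(ph$fibers$n_fib == 2)[1]
  expect_equal(m$frac[, cross], c(0.5, 0.5))
  expect_equal(m$dirs[, , cross], ph$fibers$dirs[, , cross])
  # background voxels carry no component and zero concentration
  bg <- which(ph$fibers$n_fib == 0)[1]
  expect_equal(m$n_fib[bg], 0L)
  expect_equal(m$kappa[, bg], c(0, 0))
  # higher FA yields strictly higher concentration
  single <- which(ph$fibers$n_fib == 1)
  expect_gt(cor(ph$fa_true[single], m$kappa[1, single], method = "spearman"), 0.99)
})

test_that("a DWI-derived model recovers the ground-truth fiber axes", {
  ph <- tiny_phantom()
  m <- orientation_model_from_dwi(ph$dwi)
  single <- which(ph$fibers$n_fib == 1)
  ali <- vapply(single, function(v)
    abs(sum(m$dirs[, 1, v] * ph$fibers$dirs[, 1, v])), numeric(1))
  expect_gt(median(ali), 0.999) # noise-free fits align with the truth
  expect_gt(min(ali), 0.9)
})

test_that("streamlines run straight along a coherent bundle", {
  ph <- build_phantom(default_phantom_layout(c(16L, 16L, 16L)),
                      subject_params = list(uf_coherence = 0.62,
                                            control_coherence = 0.62,
                                            st_dispersion = 0),
                      noise_sd = 0, seed = 33)
  model <- orientation_model_from_fibers(ph$fibers, ph$fa_true)
  # crank concentration to the near-deterministic regime
  model$kappa[model$kappa > 0] <- 1e6
  start <- c(9, 10.5, 10.7) # inside the seed-target bundle (x axis)
  p <- sample_streamline(start, model, tracking_params(step_size = 0.5),
                         seed = 1)
  expect_gt(nrow(p), 5)
  lateral <- sqrt((p[, 2] - p[1, 2])^2 + (p[, 3] - p[1, 3])^2)
  expect_lt(max(lateral), 0.1)
  # max_steps = 0 leaves only the start point
  p0 <- sample_streamline(start, model, tracking_params(max_steps = 0L), seed = 2)
  expect_equal(nrow(p0), 1)
  expect_equal(p0[1, ], start)
  expect_error(sample_streamline(c(-5, 0, 0), model, tracking_params()),
               "outside the grid")
})

test_that("zero concentration gives an unbiased bounded random walk", {
  dim3 <- c(21L, 21L, 21L)
  n_fib <- array(1L, dim3)
  nvox <- prod(dim3)
  dirs <- array(rep(c(1, 0, 0), nvox), c(3, 1, nvox))
  kappa <- array(1, c(1, nvox)) # above the background floor, but isotropic
  frac <- array(1, c(1, nvox))
  model <- structure(list(dim = dim3, n_fib = n_fib, dirs = dirs,
                          kappa = kappa, frac = frac),
                     class = "orientation_model")
  model$kappa[] <- 1e-2
  set.seed(3)
  disp <- t(vapply(1:500, function(i) {
    p <- sample_streamline(c(10.5, 10.5, 10.5), model,
                           tracking_params(max_steps = 30L,
                                           curvature_threshold = -1))
    p[nrow(p), ] - p[1, ]
  }, numeric(3)))
  se <- apply(disp, 2, sd) / sqrt(nrow(disp))
  expect_true(all(abs(colMeans(disp)) < 3 * se))
})

test_that("tract strength has the hit-fraction semantics", {
  ph <- default_phantom_cached()
  model <- orientation_model_from_fibers(ph$fibers, ph$fa_true)
  seedm <- threshold_mask(ph$masks$seed, 0.5)
  tgt <- threshold_mask(ph$masks$target, 0.5)
  params <- tracking_params(samples_per_seed_voxel = 50L)

  # target containing the seed: every sample is an immediate hit
  r_self <- count_hits(seedm, seedm, model, params, seed = 4)
  expect_equal(r_self$strength, 1)
  expect_equal(r_self$total_samples, 50 * r_self$n_seed_voxels)

  # unreachable target: disconnected corner, background all around
  unreach <- array(FALSE, dim(seedm)); unreach[1, 1, 1] <- TRUE
  r_un <- count_hits(seedm, unreach, model,
                     tracking_params(samples_per_seed_voxel = 50L,
                                     max_steps = 30L), seed = 5)
  expect_lt(r_un$strength, 0.01)

  # bookkeeping: strength = hits / (samples * seed voxels)
  r <- count_hits(seedm, tgt, model, params, seed = 6)
  expect_equal(r$strength, r$hits / r$total_samples)
  expect_equal(r$target_roi_size, sum(tgt))
  expect_error(count_hits(array(FALSE, dim(seedm)), tgt, model, params),
               "empty seed")
})

test_that("tracking is reproducible bit-exact under a fixed seed", {
  ph <- default_phantom_cached()
  model <- orientation_model_from_fibers(ph$fibers, ph$fa_true)
  params <- tracking_params(samples_per_seed_voxel = 100L)
  seedm <- threshold_mask(ph$masks$seed, 0.5)
  tgt <- threshold_mask(ph$masks$target, 0.5)
  a <- count_hits(seedm, tgt, model, params, seed = 7)
  b <- count_hits(seedm, tgt, model, params, seed = 7)
  expect_identical(a, b)
  curve1 <- strength_vs_dispersion_curve(c(0.1, 0.3),
                                         params = tracking_params(samples_per_seed_voxel = 50L),
                                         seed = 8)
  curve2 <- strength_vs_dispersion_curve(c(0.1, 0.3),
                                         params = tracking_params(samples_per_seed_voxel = 50L),
                                         seed = 8)
  expect_identical(curve1, curve2)
})

test_that("strength is invariant to the per-voxel sampling rate", {
  ph <- default_phantom_cached()
  model <- orientation_model_from_fibers(ph$fibers, ph$fa_true)
  seedm <- threshold_mask(ph$masks$seed, 0.5)
  tgt <- threshold_mask(ph$masks$target, 0.5)
  r1 <- count_hits(seedm, tgt, model,
                   tracking_params(samples_per_seed_voxel = 250L), seed = 9)
  r2 <- count_hits(seedm, tgt, model,
                   tracking_params(samples_per_seed_voxel = 500L), seed = 10)
  # binomial error bound on the difference of the two hit fractions
  se <- sqrt(r1$strength * (1 - r1$strength) / r1$total_samples +
               r2$strength * (1 - r2$strength) / r2$total_samples)
  expect_lt(abs(r1$strength - r2$strength), 4 * se)
})
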