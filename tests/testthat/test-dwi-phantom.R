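test_that("gradient tables have the default shell structure and unit vectors", {
  gt <- make_gradient_table(seed = 1)
  expect_equal(length(gt$bvals), 65)
  expect_equal(sum(gt$bvals == 0), 1)
  expect_equal(sum(gt$bvals == 1000), 64)
  norms <- sqrt(rowSums(gt$bvecs[gt$bvals > 0, ]^2))
  expect_true(all(abs(norms - 1) < 1e-8))
  expect_error(make_gradient_table(n_dirs = 5), "at least 6")
})

test_that("repulsion spreads directions more evenly than random draws", {
  reps <- vapply(1:5, function(s) {
    opt <- make_gradient_table(seed = s, n_iter = 150)
    set.seed(s + 100)
    rnd <- matrix(rnorm(64 * 3), ncol = 3)
    rnd <- rnd / sqrt(rowSums(rnd^2))
    min_pairwise_angle(opt$bvecs[opt$bvals > 0, ]) - min_pairwise_angle(rnd)
  }, numeric(1))
  expect_gt(median(reps), 0)
})

test_that("bval/bvec files round trip", {
  gt <- make_gradient_table(n_dirs = 12, seed = 3)
  bval <- withr::local_tempfile(fileext = ".bval")
  bvec <- withr::local_tempfile(fileext = ".bvec")
  write_bval_bvec(gt, bval, bvec)
  back <- read_bval_bvec(bval, bvec)
  expect_equal(back$bvals, gt$bvals)
  expect_equal(back$bvecs, gt$bvecs, tolerance = 1e-12)
})

test_that("single-fiber tensors have the prescribed eigenstructure", {
  D <- tensor_from_fiber(c(1, 0, 0), 1.7e-3, 0.3e-3)
  expect_equal(D, diag(c(1.7e-3, 0.3e-3, 0.3e-3)))
  expect_equal(tensor_from_fiber(c(0, 1, 0), 1e-3, 1e-3), 1e-3 * diag(3))
  R <- random_rotation(5)
  Dr <- tensor_from_fiber(R %*% c(1, 0, 0), 1.7e-3, 0.3e-3)
  expect_equal(sort(eigen(Dr, symmetric = TRUE)$values),
               sort(c(1.7e-3, 0.3e-3, 0.3e-3)), tolerance = 1e-12)
  expect_error(tensor_from_fiber(c(1, 1, 0)), "unit vector")
})

test_that("the forward signal model matches closed forms and symmetries", {
  gt <- make_gradient_table(seed = 7)
  iso <- tensor_mixture(list(list(tensor = 0.7e-3 * diag(3), fraction = 1)))
  s <- simulate_signal(iso, 1000, gt)
  expect_equal(s[gt$bvals == 0], 1000)
  expect_equal(s[gt$bvals > 0] / 1000, rep(exp(-0.7), 64), tolerance = 1e-12)

  # two orthogonal equal-fraction fibers: swapping the axes changes nothing
  mix_a <- tensor_mixture(list(
    list(tensor = tensor_from_fiber(c(1, 0, 0)), fraction = 0.5),
    list(tensor = tensor_from_fiber(c(0, 1, 0)), fraction = 0.5)))
  mix_b <- tensor_mixture(list(
    list(tensor = tensor_from_fiber(c(0, 1, 0)), fraction = 0.5),
    list(tensor = tensor_from_fiber(c(1, 0, 0)), fraction = 0.5)))
  expect_equal(simulate_signal(mix_a, 500, gt), simulate_signal(mix_b, 500, gt))
  expect_error(simulate_signal(mix_a, 500, gt, noise_sd = -1), "noise_sd")

  # noisy signals are non-negative and reproducible under seed
  n1 <- simulate_signal(mix_a, 500, gt, noise_sd = 40, seed = 8)
  n2 <- simulate_signal(mix_a, 500, gt, noise_sd = 40, seed = 8)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0))
})

test_that("noise-free signals are rotation-consistent", {
  R <- random_rotation(9)
  gt <- make_gradient_table(n_dirs = 20, seed = 10)
  gt_rot <- gt
  gt_rot$bvecs <- gt$bvecs %*% t(R)
  d0 <- c(0, 0, 1)
  mix <- tensor_mixture(list(list(tensor = tensor_from_fiber(d0), fraction = 0.7)))
  d_rot <- as.numeric(R %*% d0)
  mix_rot <- tensor_mixture(list(list(tensor = tensor_from_fiber(d_rot / sqrt(sum(d_rot^2))),
                                      fraction = 0.7)))
  expect_equal(simulate_signal(mix, 800, gt), simulate_signal(mix_rot, 800, gt_rot),
               tolerance = 1e-10)
})

test_that("the phantom has the advertised ground-truth structure", {
  ph <- tiny_phantom()
  fib <- ph$fibers
  # isotropic background has FA exactly 0
  expect_true(all(ph$fa_true[fib$n_fib == 0] == 0))
  # single-fiber voxels match the closed-form FA of (l_par, l_perp, l_perp)
  single <- which(fib$n_fib == 1)
  expect_gt(length(single), 100)
  l1 <- fib$lambda_par
  l2 <- fib$perp[1, single]
  fa_closed <- sqrt(0.5) * sqrt(2 * (l1 - l2)^2) / sqrt(l1^2 + 2 * l2^2)
  expect_equal(ph$fa_true[single], fa_closed, tolerance = 1e-12)
  # crossing voxels exist where the hook meets the corridor
  expect_gt(sum(fib$n_fib == 2), 0)
  # atlas overlap: both probability maps >= 0.10 somewhere
  both <- ph$masks$uf$prob_map >= 0.10 & ph$masks$ifof$prob_map >= 0.10
  expect_gt(sum(both), 0)
  # all masks share the grid
  for (m in ph$masks) expect_equal(dim(m$prob_map), dim(ph$fa_true))
  # layouts that leave the grid are rejected
  bad <- default_phantom_layout(c(16L, 16L, 16L))
  bad$bundles$control$pieces[[1]]$to <- c(11, 4, 40)
  expect_error(build_phantom(bad, noise_sd = 0), "exits the grid")
})

test_that("dispersion scatters the seed-target fiber axes", {
  lay <- default_phantom_layout(c(16L, 16L, 16L))
  # voxels near the seed-target bundle axis, selected geometrically
  ctr <- as.matrix(expand.grid(x = 1:16 - 0.5, y = 1:16 - 0.5,
                               z = 1:16 - 0.5))
  ax <- 16 / 24 * 16 # y = z = 10.67 in the scaled layout
  near_axis <- sqrt((ctr[, 2] - ax)^2 + (ctr[, 3] - ax)^2) < 1 &
    ctr[, 1] > 16 / 24 * 12 & ctr[, 1] < 16 / 24 * 21
  axis_spread <- vapply(c(0, 0.4), function(disp) {
    ph <- build_phantom(lay, subject_params = list(uf_coherence = 0.62,
                                                   control_coherence = 0.62,
                                                   st_dispersion = disp),
                        noise_sd = 0, seed = 77)
    st_vox <- which(near_axis & ph$fibers$n_fib == 1)
    dx <- abs(ph$fibers$dirs[1, 1, st_vox]) # |cos| of angle to the x axis
    mean(acos(pmin(dx, 1)))
  }, numeric(1))
  expect_equal(axis_spread[1], 0, tolerance = 1e-8)
  expect_gt(axis_spread[2], 0.1)
})

test_that("NIfTI probability maps round trip exactly", {
  ph <- tiny_phantom()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$masks$uf$prob_map, path, 2)
  back <- read_volume_nifti(path)
  expect_identical(dim(back), dim(ph$masks$uf$prob_map))
  expect_identical(as.numeric(back), as.numeric(ph$masks$uf$prob_map))
})

test_that("Rician noise at SNR 20 perturbs single-fiber FA by < 0.05", {
  gt <- make_gradient_table(seed = 21)
  D <- tensor_from_fiber(c(0, 1, 0), 1.7e-3, 0.5e-3)
  fa_true <- fit_tensor(simulate_signal(
    tensor_mixture(list(list(tensor = D, fraction = 1))), 1000, gt), gt)$fa
  set.seed(22)
  errs <- vapply(1:100, function(i) {
    s <- simulate_signal(tensor_mixture(list(list(tensor = D, fraction = 1))),
                         1000, gt, noise_sd = 50)
    abs(fit_tensor(s, gt)$fa - fa_true)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
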