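# Digital diffusion phantoms: coherent fiber bundles (a curved
# fronto-temporal "UF-like" hook whose anterior limb runs inside a larger
# "IFOF-like" corridor, a control bundle, and a short seed-to-target bundle
# between two compact ROIs), embedded in isotropic background, plus
# probabilistic atlas-style masks of each bundle.

#' Single-fiber diffusion tensor
#'
#' Axially symmetric tensor `D = lambda_perp * I + (lambda_par -
#' lambda_perp) * d d^T` with eigenvalues `(lambda_par, lambda_perp,
#' lambda_perp)` and principal eigenvector `d`.
#'
#' @param direction Unit 3-vector (tolerance 1e-6 on the norm).
#' @param lambda_par Axial diffusivity, mm^2/s.
#' @param lambda_perp Radial diffusivity, mm^2/s (`0 < lambda_perp <=
#'   lambda_par`).
#' @return A 3x3 symmetric positive-definite matrix.
#' @export
tensor_from_fiber <- function(direction, lambda_par = 1.7e-3,
                              lambda_perp = 0.3e-3) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("direction must be a unit vector")
  if (!(lambda_par >= lambda_perp && lambda_perp > 0))
    stop("need lambda_par >= lambda_perp > 0")
  lambda_perp * diag(3) + (lambda_par - lambda_perp) * tcrossprod(direction)
}

#' Mixture description for the forward signal model
#'
#' @param components List of components, each a list with `tensor` (3x3) and
#'   `fraction` (0-1); fractions must sum to at most 1, the remainder
#'   diffuses isotropically.
#' @param iso_diffusivity Isotropic diffusivity of the remainder, mm^2/s.
#' @return A `tensor_mixture`.
#' @export
tensor_mixture <- function(components = list(), iso_diffusivity = 0.8e-3) {
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (length(fr) && (any(fr < 0) || sum(fr) > 1 + 1e-9))
    stop("fractions must be in [0,1] and sum to <= 1")
  structure(list(components = components, iso_diffusivity = iso_diffusivity),
            class = "tensor_mixture")
}

#' Forward diffusion signal of a tensor mixture
#'
#' Standard multi-tensor Stejskal-Tanner model
#' `S = S0 * (sum_k f_k exp(-b g' D_k g) + f_iso exp(-b d_iso))`, optionally
#' corrupted with Rician noise (magnitude of a complex Gaussian
#' perturbation, the noise model of magnitude MR images). Signals are never
#' negative.
#'
#' @param mixture A [tensor_mixture()].
#' @param S0 Non-weighted baseline signal (> 0).
#' @param gtab A `gradient_table`.
#' @param noise_sd Rician noise SD in signal units (0 = noise-free).
#' @param seed RNG seed for the noise.
#' @return Numeric signal vector, one entry per volume.
#' @export
simulate_signal <- function(mixture, S0, gtab, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(mixture, "tensor_mixture"), S0 > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  b <- gtab$bvals
  g <- gtab$bvecs
  fr <- vapply(mixture$components, `[[`, numeric(1), "fraction")
  s <- rep(0, length(b))
  for (comp in mixture$components) {
    adc <- rowSums((g %*% comp$tensor) * g)
    s <- s + comp$fraction * exp(-b * adc)
  }
  f_iso <- 1 - sum(fr)
  if (f_iso > 1e-12) s <- s + f_iso * exp(-b * mixture$iso_diffusivity)
  s <- S0 * s
  if (noise_sd > 0) {
    maybe_set_seed(seed)
    s <- sqrt((s + rnorm(length(s), 0, noise_sd))^2 +
                rnorm(length(s), 0, noise_sd)^2)
  }
  s
}

#' ROI mask container
#'
#' @param prob_map Array of per-voxel probabilities in `[0, 1]`.
#' @param name Label.
#' @param kind One of `"tract-atlas"`, `"seed"`, `"target"`, `"control"`.
#' @return An `roi_mask`.
#' @export
roi_mask <- function(prob_map, name, kind = c("tract-atlas", "seed",
                                              "target", "control")) {
  kind <- match.arg(kind)
  if (any(prob_map < 0 | prob_map > 1)) stop("probabilities must be in [0,1]")
  structure(list(prob_map = prob_map, name = name, kind = kind),
            class = "roi_mask")
}

# Separable 3-D Gaussian smoothing with a normalized truncated kernel.
gaussian_smooth_3d <- function(x, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(x)
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (j in (-r):r) {
      idx <- clamp(seq_len(d[axis]) + j, 1L, d[axis]) # replicate-pad edges
      sl <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + k[j + r + 1] * sl
    }
    out
  }
  conv_axis(conv_axis(conv_axis(x, 1L), 2L), 3L)
}

# -- geometry helpers (all in voxel units; voxel i spans [i, i+1),
#    center i + 0.5; world affine is diag(voxel_size) with RAS axes) -------

# Sample a path (list of straight/arc pieces) into points + unit tangents.
sample_path <- function(pieces, step = 0.25) {
  pts <- NULL; tans <- NULL
  for (pc in pieces) {
    if (pc$type == "line") {
      a <- pc$from; b <- pc$to
      len <- sqrt(sum((b - a)^2))
      tt <- seq(0, 1, length.out = max(2, ceiling(len / step)))
      p <- outer(1 - tt, a) + outer(tt, b)
      tn <- matrix(rep((b - a) / len, each = nrow(p)), ncol = 3)
    } else if (pc$type == "arc") {
      # circle of radius r about center, in the plane spanned by (u, v)
      arc_len <- pc$radius * abs(diff(pc$theta))
      th <- seq(pc$theta[1], pc$theta[2],
                length.out = max(2, ceiling(arc_len / step)))
      p <- t(vapply(th, function(t0) pc$center + pc$radius *
                      (cos(t0) * pc$u + sin(t0) * pc$v), numeric(3)))
      tn <- t(vapply(th, function(t0) -sin(t0) * pc$u + cos(t0) * pc$v,
                     numeric(3)))
      if (diff(pc$theta) < 0) tn <- -tn
    } else stop("unknown path piece type: ", pc$type)
    pts <- rbind(pts, p); tans <- rbind(tans, tn)
  }
  list(points = pts, tangents = tans)
}

# Distance from every voxel center to the sampled path; nearest tangent.
voxel_membership <- function(dim3, path, radius) {
  ctr <- as.matrix(expand.grid(x = seq_len(dim3[1]) - 0.5,
                               y = seq_len(dim3[2]) - 0.5,
                               z = seq_len(dim3[3]) - 0.5))
  p <- path$points
  d2min <- rep(Inf, nrow(ctr)); nearest <- rep(1L, nrow(ctr))
  for (i in seq_len(nrow(p))) {
    d2 <- (ctr[, 1] - p[i, 1])^2 + (ctr[, 2] - p[i, 2])^2 +
      (ctr[, 3] - p[i, 3])^2
    upd <- d2 < d2min
    d2min[upd] <- d2[upd]; nearest[upd] <- i
  }
  inside <- d2min <= radius^2
  list(inside = array(inside, dim3),
       tangent = path$tangents[nearest, , drop = FALSE])
}

#' Default phantom layout
#'
#' Geometry (voxel units) of the four bundles and the seed/target ROIs on a
#' 24^3 grid of 2 mm voxels:
#' * `ifof`: straight anterior-posterior corridor, radius 2.4;
#' * `uf`: hook — an anterior limb lying *inside* the IFOF corridor, a
#'   quarter-circle descent, and a short inferior limb — radius 1.6, so the
#'   two atlas masks overlap anteriorly and cross where the hook turns;
#' * `control`: straight inferior-superior bundle away from both;
#' * `st`: short left-right seed-to-target bundle, radius 1.8 (one voxel of
#'   lateral buffer around the seed/target cross-section), with
#'   spherical `seed` and `target` ROIs at its ends.
#'
#' @param grid_dim Grid dimensions (>= 16 each for this layout).
#' @param voxel_size Isotropic voxel size, mm.
#' @return A `phantom_layout` list.
#' @export
default_phantom_layout <- function(grid_dim = c(24L, 24L, 24L),
                                   voxel_size = 2) {
  if (any(grid_dim < 16)) stop("default layout needs a grid of at least 16^3")
  s <- grid_dim / 24 # scale geometry with the grid
  sc <- function(v) v * s
  structure(list(
    grid_dim = as.integer(grid_dim), voxel_size = voxel_size,
    bundles = list(
      ifof = list(radius = 2.4 * min(s), pieces = list(
        list(type = "line", from = sc(c(6, 2, 12)), to = sc(c(6, 21, 12))))),
      uf = list(radius = 1.6 * min(s), pieces = list(
        list(type = "line", from = sc(c(6, 4, 12)), to = sc(c(6, 8, 12))),
        list(type = "arc", center = sc(c(6, 8, 6)), radius = 6 * min(s),
             u = c(0, 0, 1), v = c(0, 1, 0), theta = c(0, pi / 2)),
        list(type = "line", from = sc(c(6, 14, 6)), to = sc(c(6, 14, 3))))),
      control = list(radius = 1.6 * min(s), pieces = list(
        list(type = "line", from = sc(c(17, 6, 2)), to = sc(c(17, 6, 21))))),
      st = list(radius = 1.8 * min(s), pieces = list(
        list(type = "line", from = sc(c(12, 16, 16)), to = sc(c(21, 16, 16)))))
    ),
    seed_center = sc(c(12.5, 16, 16)), seed_radius = 1.5 * min(s),
    target_center = sc(c(20.5, 16, 16)), target_radius = 1.6 * min(s)
  ), class = "phantom_layout")
}

sphere_mask <- function(dim3, center, radius) {
  ctr <- as.matrix(expand.grid(x = seq_len(dim3[1]) - 0.5,
                               y = seq_len(dim3[2]) - 0.5,
                               z = seq_len(dim3[3]) - 0.5))
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 +
    (ctr[, 3] - center[3])^2
  array(d2 <= radius^2, dim3)
}

#' Build a subject's diffusion phantom
#'
#' Assembles the fiber field from the layout and the subject's physical
#' parameters, simulates the diffusion-weighted volume, and derives the
#' ground-truth FA map and all ROI masks. Single-bundle voxels hold one pure
#' fiber tensor (so noise-free tensor fits recover it exactly); voxels
#' where two bundles meet hold an equal-fraction crossing; everything else
#' diffuses isotropically. Atlas probability maps are the bundle indicator
#' maps smoothed with a Gaussian (sigma = 1 voxel).
#'
#' @param layout A [default_phantom_layout()] (or compatible list).
#' @param subject_params One row of [phantom_params_from_traits()] (list or
#'   data.frame row with `uf_coherence`, `control_coherence`,
#'   `st_dispersion`); `NULL` uses coherence 0.62 everywhere and dispersion
#'   0.1.
#' @param noise_sd Rician noise SD (signal units; `S0` is 1000). Default
#'   `S0/30`.
#' @param seed RNG seed (noise and fiber-direction jitter).
#' @param lambda_par Axial diffusivity of all bundles, mm^2/s.
#' @param iso_diffusivity Background diffusivity, mm^2/s.
#' @param S0 Baseline signal.
#' @return A list: `dwi` (a `dwi_volume`: 4-D `signal`, `gtab`,
#'   `voxel_size`, `S0`), `fa_true` (3-D array; closed-form FA in
#'   single-fiber voxels, composite-tensor FA in crossings, 0 in
#'   background), `masks` (named `roi_mask` list: `uf`, `ifof`, `control`,
#'   `st`, `seed`, `target`), and `fibers` (the per-voxel fiber field used
#'   for tracking ground truth).
#' @export
build_phantom <- function(layout = default_phantom_layout(),
                          subject_params = NULL, noise_sd = 1000 / 30,
                          seed = NULL, lambda_par = 1.7e-3,
                          iso_diffusivity = 0.8e-3, S0 = 1000) {
  maybe_set_seed(seed)
  dim3 <- layout$grid_dim
  if (is.null(subject_params))
    subject_params <- list(uf_coherence = 0.62, control_coherence = 0.62,
                           st_dispersion = 0.1)
  coh <- list(uf = subject_params$uf_coherence,
              ifof = 0.62,
              control = subject_params$control_coherence,
              st = 0.70)
  # membership and tangents per bundle
  memb <- lapply(names(layout$bundles), function(nm) {
    bd <- layout$bundles[[nm]]
    path <- sample_path(bd$pieces)
    if (any(path$points < 0 | sweep(path$points, 2, dim3, `>`)))
      stop("bundle '", nm, "' exits the grid: layout error")
    voxel_membership(dim3, path, bd$radius)
  })
  names(memb) <- names(layout$bundles)

  nvox <- prod(dim3)
  kmax <- 2L
  n_fib <- array(0L, dim3)
  dirs <- array(0, c(3, kmax, nvox))
  perp <- array(0, c(kmax, nvox))
  frac <- array(0, c(kmax, nvox))

  for (nm in names(memb)) {
    m <- memb[[nm]]
    idx <- which(m$inside)
    if (!length(idx)) next
    dvec <- m$tangent[idx, , drop = FALSE]
    if (nm == "st" && subject_params$st_dispersion > 0) {
      # tangent-plane Gaussian jitter of the fiber axis (small-angle model)
      eps <- matrix(rnorm(length(idx) * 3, 0, subject_params$st_dispersion),
                    ncol = 3)
      eps <- eps - dvec * rowSums(eps * dvec)
      dvec <- dvec + eps
      dvec <- dvec / sqrt(rowSums(dvec^2))
    }
    lperp <- lambda_par * (1 - coh[[nm]])
    for (j in seq_along(idx)) {
      v <- idx[j]
      k <- n_fib[v]
      d_new <- dvec[j, ]
      if (k > 0) {
        # nearly parallel with an existing population: keep the first
        dots <- abs(colSums(dirs[, seq_len(k), v, drop = FALSE] *
                              d_new))
        if (any(dots > 0.92)) next
      }
      if (k >= kmax) next
      n_fib[v] <- k + 1L
      dirs[, k + 1L, v] <- d_new
      perp[k + 1L, v] <- lperp
    }
  }
  # fractions: single fiber -> 1; crossing -> 0.5 each
  for_one <- which(n_fib == 1L); for_two <- which(n_fib == 2L)
  frac[1, for_one] <- 1
  frac[1, for_two] <- 0.5; frac[2, for_two] <- 0.5

  fibers <- list(dim = dim3, n_fib = n_fib, dirs = dirs, perp = perp,
                 frac = frac, lambda_par = lambda_par,
                 iso_diffusivity = iso_diffusivity)

  # ground-truth FA
  fa_true <- array(0, dim3)
  if (length(for_one)) {
    l1 <- lambda_par; l2 <- perp[1, for_one]
    fa_true[for_one] <- fa_from_eigenvalues_vec(l1, l2, l2)
  }
  for (v in for_two) {
    D <- 0.5 * tensor_from_fiber(dirs[, 1, v], lambda_par, perp[1, v]) +
      0.5 * tensor_from_fiber(dirs[, 2, v], lambda_par, perp[2, v])
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    fa_true[v] <- fa_from_eigenvalues(ev[1], ev[2], ev[3])
  }

  # simulate the DWI signal, vectorized over voxels
  gtab <- make_gradient_table()
  nvol <- length(gtab$bvals)
  sig <- matrix(S0 * exp(-gtab$bvals * iso_diffusivity), nvol, nvox)
  fib_idx <- which(n_fib > 0L)
  if (length(fib_idx)) {
    acc <- matrix(0, nvol, length(fib_idx))
    f_iso_col <- 1 - colSums(frac[, fib_idx, drop = FALSE])
    for (k in seq_len(kmax)) {
      has_k <- n_fib[fib_idx] >= k
      if (!any(has_k)) next
      cols <- which(has_k)
      dk <- dirs[, k, fib_idx[cols], drop = FALSE] # 3 x ncols
      dot <- gtab$bvecs %*% dk[, 1, ]              # nvol x ncols
      lperp_k <- perp[k, fib_idx[cols]]
      adc <- matrix(lperp_k, nvol, length(cols), byrow = TRUE) +
        (lambda_par - matrix(lperp_k, nvol, length(cols), byrow = TRUE)) * dot^2
      ek <- exp(-gtab$bvals * adc)
      acc[, cols] <- acc[, cols] +
        matrix(frac[k, fib_idx[cols]], nvol, length(cols), byrow = TRUE) * ek
    }
    acc <- acc + outer(exp(-gtab$bvals * iso_diffusivity), f_iso_col)
    sig[, fib_idx] <- S0 * acc
  }
  if (noise_sd > 0)
    sig <- sqrt((sig + rnorm(length(sig), 0, noise_sd))^2 +
                  rnorm(length(sig), 0, noise_sd)^2)
  signal <- aperm(array(sig, c(nvol, dim3)), c(2, 3, 4, 1))

  dwi <- structure(list(signal = signal, gtab = gtab,
                        voxel_size = layout$voxel_size, S0 = S0),
                   class = "dwi_volume")

  masks <- list(
    uf = roi_mask(gaussian_smooth_3d(memb$uf$inside * 1), "uf", "tract-atlas"),
    ifof = roi_mask(gaussian_smooth_3d(memb$ifof$inside * 1), "ifof",
                    "tract-atlas"),
    control = roi_mask(gaussian_smooth_3d(memb$control$inside * 1), "control",
                       "control"),
    st = roi_mask(gaussian_smooth_3d(memb$st$inside * 1), "st", "tract-atlas"),
    seed = roi_mask(sphere_mask(dim3, layout$seed_center,
                                layout$seed_radius) * 1, "seed", "seed"),
    target = roi_mask(sphere_mask(dim3, layout$target_center,
                                  layout$target_radius) * 1, "target",
                      "target")
  )
  list(dwi = dwi, fa_true = fa_true, masks = masks, fibers = fibers,
       layout = layout)
}

#' Write / read NIfTI volumes
#'
#' Thin wrappers over RNifti with the package's affine convention (diagonal
#' voxel-size affine, RAS axes).
#'
#' @param vol 3-D or 4-D array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size Isotropic voxel size, mm.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = 2) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @return The array (attributes dropped).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  arr
}
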