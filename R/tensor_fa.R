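# Log-linear least-squares diffusion tensor fitting, FA maps, and mean FA
# within thresholded / exclusive atlas masks.

# Design matrix mapping (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) to ln S.
tensor_design_matrix <- function(gtab) {
  b <- gtab$bvals
  g <- gtab$bvecs
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

beta_to_tensor <- function(beta) {
  matrix(c(beta[2], beta[5], beta[6],
           beta[5], beta[3], beta[7],
           beta[6], beta[7], beta[4]), 3, 3)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' sqrt(l1^2 + l2^2 + l3^2)`. Negative eigenvalues (possible in noisy
#' log-linear fits) are clamped to zero before evaluation so the result
#' stays in `[0, 1]`; the raw tensor is never altered by this.
#'
#' @param l1,l2,l3 Tensor eigenvalues (any order).
#' @return FA in `[0, 1]`; error if all eigenvalues are zero.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  out <- fa_from_eigenvalues_vec(l1, l2, l3)
  if (is.na(out)) stop("FA undefined: all eigenvalues are zero")
  out
}

# vectorized core; returns NA where all eigenvalues are 0
fa_from_eigenvalues_vec <- function(l1, l2, l3) {
  l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  den <- l1^2 + l2^2 + l3^2
  num <- (l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2
  out <- sqrt(0.5) * sqrt(num) / sqrt(den)
  out[den == 0] <- NA_real_
  clamp(out, 0, 1)
}

#' Fit a diffusion tensor to one voxel's signal
#'
#' Ordinary (unweighted) log-linear least squares on
#' `ln S = ln S0 - b g' D g`, the classic default of standard tensor-fitting
#' tools; weighted least squares (weights `S^2`) is available via
#' `wls = TRUE`. Non-positive signals are floored at `1e-6 * max(signal)`
#' before the log. Negative eigenvalues are clamped to zero for FA only; the
#' raw tensor is returned as fitted.
#'
#' @param signal Numeric signal vector, one entry per volume.
#' @param gtab A `gradient_table` (needs >= 1 b0 and >= 6 non-collinear
#'   weighted directions; a rank-deficient design is an error).
#' @param wls Use one-pass weighted least squares.
#' @return A `tensor_result`: `tensor` (3x3), `eigenvalues` (descending),
#'   `principal_direction`, `S0_fit`, `fa`.
#' @export
fit_tensor <- function(signal, gtab, wls = FALSE) {
  if (length(signal) != length(gtab$bvals))
    stop("signal length must match the gradient table")
  if (sum(gtab$bvals > 0) < 6 || sum(gtab$bvals == 0) < 1)
    stop("unidentifiable fit: need >= 1 b0 and >= 6 weighted volumes")
  X <- tensor_design_matrix(gtab)
  if (qr(X)$rank < 7L)
    stop("unidentifiable fit: rank-deficient design (collinear directions)")
  s <- pmax(signal, 1e-6 * max(signal))
  y <- log(s)
  if (wls) {
    w <- s^2
    beta <- solve(crossprod(X * w, X), crossprod(X * w, y))
  } else {
    beta <- solve(crossprod(X), crossprod(X, y))
  }
  D <- beta_to_tensor(beta)
  e <- eigen(D, symmetric = TRUE)
  structure(list(tensor = D, eigenvalues = e$values,
                 principal_direction = e$vectors[, 1],
                 S0_fit = exp(beta[1]),
                 fa = fa_from_eigenvalues_vec(e$values[1], e$values[2],
                                              e$values[3])),
            class = "tensor_result")
}

#' Whole-volume FA map
#'
#' Voxelwise log-linear tensor fit (vectorized over the grid) followed by
#' the FA formula. Background voxels, defined as mean b0 signal below
#' `background_floor`, are set to FA 0 and skipped.
#'
#' @param dwi A `dwi_volume` (from [build_phantom()] or assembled manually).
#' @param wls Weighted least squares (see [fit_tensor()]).
#' @param background_floor Mean-b0 threshold below which a voxel is treated
#'   as background.
#' @return 3-D FA array in `[0, 1]`.
#' @export
fa_map <- function(dwi, wls = FALSE, background_floor = 1e-3) {
  sig <- dwi$signal
  d <- dim(sig)
  if (length(d) != 4 || d[4] != length(dwi$gtab$bvals))
    stop("signal grid does not match the gradient table")
  nvox <- prod(d[1:3])
  smat <- matrix(aperm(sig, c(4, 1, 2, 3)), d[4], nvox)
  b0_mean <- colMeans(smat[dwi$gtab$bvals == 0, , drop = FALSE])
  fg <- which(b0_mean >= background_floor)
  fa <- numeric(nvox)
  if (length(fg)) {
    X <- tensor_design_matrix(dwi$gtab)
    if (qr(X)$rank < 7L) stop("rank-deficient gradient design")
    s <- smat[, fg, drop = FALSE]
    s <- pmax(s, 1e-6 * matrix(apply(s, 2, max), d[4], length(fg),
                               byrow = TRUE))
    if (wls) {
      fa[fg] <- vapply(seq_along(fg), function(j)
        fit_tensor(smat[, fg[j]], dwi$gtab, wls = TRUE)$fa, numeric(1))
    } else {
      beta <- solve(crossprod(X), crossprod(X, log(s))) # 7 x nfg
      fa[fg] <- vapply(seq_along(fg), function(j) {
        ev <- eigen(beta_to_tensor(beta[, j]), symmetric = TRUE,
                    only.values = TRUE)$values
        fa_from_eigenvalues_vec(ev[1], ev[2], ev[3])
      }, numeric(1))
    }
  }
  fa[is.na(fa)] <- 0
  array(fa, d[1:3])
}

#' Threshold a probabilistic ROI mask
#'
#' A voxel is included iff its probability is `>=` the threshold (inclusive
#' comparison, so behavior at the default 10% boundary is deterministic).
#'
#' @param mask An `roi_mask` or probability array.
#' @param threshold Probability cutoff in `[0, 1]`; default 0.10.
#' @return Logical 3-D array.
#' @export
threshold_mask <- function(mask, threshold = 0.10) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  pm <- if (inherits(mask, "roi_mask")) mask$prob_map else mask
  out <- pm >= threshold
  if (!any(out)) warning("thresholded mask is empty")
  out
}

#' Set difference of two binary masks
#'
#' `a & !b`: the voxels of `a` with every voxel of `b` removed. Used to
#' study the portion of a tract that does not overlap another (e.g. an
#' occipito-frontal corridor with the overlapping fronto-temporal hook
#' excluded).
#'
#' @param a,b Logical arrays on the same grid.
#' @return Logical array.
#' @export
exclusive_mask <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks are on different grids")
  a & !b
}

#' Mean FA within a binary mask
#'
#' @param fa 3-D FA array.
#' @param mask Logical array on the same grid (must select >= 1 voxel; an
#'   empty mask is an error signalling over-thresholding).
#' @param roi_name Label recorded in the result.
#' @param threshold Threshold recorded in the result (bookkeeping only).
#' @return A `masked_fa_stat`: `roi_name`, `threshold`, `n_voxels`,
#'   `mean_fa`.
#' @export
mean_fa <- function(fa, mask, roi_name = "roi", threshold = NA_real_) {
  if (!identical(dim(fa), dim(mask))) stop("FA map and mask grids differ")
  n <- sum(mask)
  if (n < 1) stop("empty mask: no voxels survive thresholding")
  structure(list(roi_name = roi_name, threshold = threshold,
                 n_voxels = n, mean_fa = mean(fa[mask])),
            class = "masked_fa_stat")
}

#' Write masked-FA statistics to TSV
#' @param stats List of `masked_fa_stat` objects.
#' @param path Output path.
#' @export
write_fa_stats_tsv <- function(stats, path) {
  df <- do.call(rbind, lapply(stats, function(s)
    data.frame(roi_name = s$roi_name, threshold = s$threshold,
               n_voxels = s$n_voxels, mean_fa = s$mean_fa)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
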