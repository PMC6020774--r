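# Diffusion gradient schemes.

#' Build a diffusion gradient table
#'
#' Generates `n_dirs` diffusion-sensitizing directions approximately uniform
#' over the sphere (electrostatic repulsion between antipodal point pairs,
#' refined from a random initialization) plus `n_b0` non-weighted reference
#' volumes, emulating a single-shell acquisition. The default is the
#' 64-direction, b = 1000 s/mm^2 scheme with one b0.
#'
#' @param n_dirs Number of diffusion-weighted directions (>= 6; the tensor
#'   is unidentifiable below six non-collinear directions).
#' @param b b-value of the weighted volumes, s/mm^2.
#' @param n_b0 Number of b = 0 volumes (prepended).
#' @param seed RNG seed for the initialization.
#' @param n_iter Repulsion iterations.
#' @return A `gradient_table`: `bvals` (length `n_b0 + n_dirs`), `bvecs`
#'   (matrix, rows matching `bvals`; zero rows for b0), `n_b0`.
#' @export
make_gradient_table <- function(n_dirs = 64L, b = 1000, n_b0 = 1L,
                                seed = NULL, n_iter = 200L) {
  if (n_dirs < 6) stop("at least 6 directions are required")
  maybe_set_seed(seed)
  p <- matrix(rnorm(n_dirs * 3), ncol = 3)
  p <- p / sqrt(rowSums(p^2))
  lr <- 0.1
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n_dirs, 3)
    for (i in seq_len(n_dirs)) {
      d1 <- sweep(p[-i, , drop = FALSE], 2, p[i, ], function(a, b) b - a)
      d2 <- sweep(-p[-i, , drop = FALSE], 2, p[i, ], function(a, b) b - a)
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      f[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    # project forces onto the tangent plane and step
    f <- f - p * rowSums(f * p)
    p <- p + lr * f / max(sqrt(rowSums(f^2)), 1e-9)
    p <- p / sqrt(rowSums(p^2))
    lr <- lr * 0.98
  }
  bvals <- c(rep(0, n_b0), rep(b, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), p)
  structure(list(bvals = bvals, bvecs = bvecs, n_b0 = as.integer(n_b0)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("Gradient table: %d volumes (%d b0 + %d weighted, b = %s s/mm^2)\n",
              length(x$bvals), x$n_b0, sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = ",")))
  invisible(x)
}

#' Minimum pairwise angle of a direction set
#'
#' Angles are taken between axes (direction and its negation identified), in
#' radians. Used to assess the uniformity of a gradient scheme.
#'
#' @param bvecs Matrix of unit direction rows.
#' @return Smallest pairwise axial angle, radians.
#' @export
min_pairwise_angle <- function(bvecs) {
  g <- abs(bvecs %*% t(bvecs))
  diag(g) <- -Inf
  acos(clamp(max(g[upper.tri(g)]), -1, 1))
}

#' Write / read FSL-style bval and bvec text files
#'
#' `bval` is a single space-separated row; `bvec` is three rows (x, y, z
#' components, one column per volume).
#'
#' @param gtab A `gradient_table`.
#' @param bval_path,bvec_path Output paths.
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- do.call(rbind, lapply(readLines(bvec_path), function(l)
    scan(text = l, quiet = TRUE)))
  if (nrow(bv) != 3 || ncol(bv) != length(bvals))
    stop("bvec must have 3 rows and one column per bval entry")
  structure(list(bvals = bvals, bvecs = t(bv), n_b0 = sum(bvals == 0)),
            class = "gradient_table")
}
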