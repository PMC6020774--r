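# Brain-behavior statistical battery: one-tailed Pearson and partial
# correlations, Steiger's test for dependent correlations sharing one
# variable, and Benjamini-Hochberg FDR over the battery.

new_correlation_result <- function(r, n, df, t_or_z, p_raw, tail,
                                   covariates = character(0)) {
  structure(list(r = r, n = n, df = df, t_or_z = t_or_z, p_raw = p_raw,
                 p_fdr = NA_real_, tail = tail, covariates = covariates),
            class = "correlation_result")
}

check_corr_input <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < min_n) stop("need at least ", min_n, " observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
}

#' One-tailed Pearson correlation
#'
#' Pearson's r with the one-tailed test of a positive association:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, `p = P(T_{n-2} > t)`. The positive
#' tail is the package default because the directional hypotheses of the
#' analysis (more coherent pathway, better performance) are fixed a priori;
#' `tail = "two"` is available.
#'
#' @param x,y Numeric vectors.
#' @param tail `"one"` (positive association) or `"two"`.
#' @return A `correlation_result` (`r`, `n`, `df = n - 2`, `t_or_z`,
#'   `p_raw`, `tail`).
#' @export
pearson_one_tailed <- function(x, y, tail = c("one", "two")) {
  tail <- match.arg(tail)
  check_corr_input(x, y, 3L)
  n <- length(x)
  r <- cor(x, y)
  r <- clamp(r, -1, 1)
  df <- n - 2L
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
  }
  p <- if (tail == "one") pt(t, df, lower.tail = FALSE)
       else 2 * pt(-abs(t), df)
  new_correlation_result(r, n, df, t, p, tail)
}

#' One-tailed partial correlation controlling one covariate
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' equivalently the correlation of the residuals of `x` and `y` after
#' regressing each on `z`; tested on `df = n - 3`.
#'
#' @param x,y Numeric vectors.
#' @param z Covariate vector (an error if perfectly collinear with `x` or
#'   `y`).
#' @param tail `"one"` (positive association) or `"two"`.
#' @return A `correlation_result` with `df = n - 3` and the covariate noted.
#' @export
partial_corr_one_tailed <- function(x, y, z, tail = c("one", "two")) {
  tail <- match.arg(tail)
  check_corr_input(x, y, 4L)
  if (length(z) != length(x)) stop("covariate length mismatch")
  if (sd(z) == 0) stop("degenerate covariate: zero variance")
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate covariate: collinear with x or y")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- clamp(r, -1, 1)
  n <- length(x)
  df <- n - 3L
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- if (tail == "one") pt(t, df, lower.tail = FALSE)
       else 2 * pt(-abs(t), df)
  new_correlation_result(r, n, df, t, p, tail, covariates = "z")
}

check_psd_triple <- function(r12, r13, r23) {
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("correlation triple (r12, r13, r23) is not positive semidefinite")
}

#' Steiger's Z1* test for two dependent correlations sharing one variable
#'
#' Tests `H0: rho12 = rho13` for correlations measured on the same sample
#' and sharing variable 1 (e.g. the same behavioral score against two
#' tracts, or the same tract against two behavioral scores), with `r23` the
#' correlation between the two non-shared variables. Fisher-transforms `r12`
#' and `r13` and divides their difference by its sampling SD using the
#' Dunn-Clark covariance evaluated at the pooled estimate
#' `rbar = (r12 + r13) / 2`:
#' `z = (z12 - z13) * sqrt((n - 3) / (2 - 2 s))`, where
#' `s = psi / (1 - rbar^2)^2` and
#' `psi = r23 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r23^2) / 2`.
#' Two-tailed normal p. A variant using Williams' t is available.
#'
#' @param r12,r13 The two dependent correlations being compared.
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @param method `"steiger"` (Z1*) or `"williams"` (Williams' t1).
#' @return A `steiger_comparison`: `r12`, `r13`, `r23`, `n`, `z`,
#'   `p_two_tailed`, `method`.
#' @export
steiger_z <- function(r12, r13, r23, n, method = c("steiger", "williams")) {
  method <- match.arg(method)
  if (n < 4) stop("n must be >= 4")
  if (any(abs(c(r12, r13, r23)) > 1)) stop("correlations must be in [-1, 1]")
  check_psd_triple(r12, r13, r23)
  if (method == "steiger") {
    z12 <- atanh(r12); z13 <- atanh(r13)
    rbar <- (r12 + r13) / 2
    psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
    s <- psi / (1 - rbar^2)^2
    z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * s))
    p <- 2 * pnorm(-abs(z))
  } else {
    # Williams' t1 for the same hypothesis
    detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
    rbar <- (r12 + r13) / 2
    t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) /
      (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
    z <- t
    p <- 2 * pt(-abs(t), df = n - 3)
  }
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = n, z = z,
                 p_two_tailed = p, method = method),
            class = "steiger_comparison")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via `stats::p.adjust(method = "BH")`): sort the m
#' raw p-values ascending, take `p(i) * m / i`, enforce monotonicity by a
#' running minimum from the largest rank down, cap at 1, and return in the
#' original order. Adjusted values are never smaller than the raw values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# ---- the battery -----------------------------------------------------------

#' Battery specification
#'
#' Defines which brain-behavior correlations and dependent-correlation
#' comparisons a battery run computes. The FDR family defaults to *all*
#' correlation tests of the run (simple and partial together); Steiger
#' comparisons are reported as raw two-tailed p-values and are not part of
#' the FDR family.
#'
#' @param fa_columns Cohort columns holding per-tract mean FA (each is
#'   correlated with every behavior column, one-tailed).
#' @param strength_columns Cohort columns holding tract strengths (partial
#'   correlations controlling `covariate`).
#' @param behavior_columns Behavioral measures.
#' @param covariate Covariate column for the tract-strength partial
#'   correlations (e.g. target-ROI size); `NULL` for simple correlations.
#' @param comparisons List of Steiger comparisons, each a list
#'   `list(label =, shared =, a =, b =)` meaning corr(shared, a) vs
#'   corr(shared, b). The default battery compares each brain measure's
#'   high-value against low-value recall correlation, plus left-vs-right
#'   FA for the first bundle pair found.
#' @param q Nominal FDR level.
#' @return A `battery_spec`.
#' @export
battery_spec <- function(fa_columns = c("fa_uf_left", "fa_uf_right",
                                        "fa_control"),
                         strength_columns = "ts_nacc_vta",
                         behavior_columns = c("mean_high_recall",
                                              "mean_low_recall",
                                              "mean_selectivity"),
                         covariate = "target_size",
                         comparisons = NULL, q = 0.05) {
  if (is.null(comparisons)) {
    comparisons <- lapply(c(fa_columns, strength_columns), function(cc)
      list(label = paste0(cc, ": high_vs_low"), shared = cc,
           a = behavior_columns[1], b = behavior_columns[2]))
    lr <- grep("left$", fa_columns, value = TRUE)
    for (lc in lr) {
      rc <- sub("left$", "right", lc)
      if (rc %in% fa_columns)
        comparisons <- c(comparisons, list(list(
          label = paste0(lc, "_vs_", rc, ": high"),
          shared = behavior_columns[1], a = lc, b = rc)))
    }
  }
  structure(list(fa_columns = fa_columns,
                 strength_columns = strength_columns,
                 behavior_columns = behavior_columns,
                 covariate = covariate, comparisons = comparisons, q = q),
            class = "battery_spec")
}

#' Run the brain-behavior correlation battery
#'
#' Computes every configured correlation (one-tailed positive), adjusts the
#' whole family with Benjamini-Hochberg, runs the configured Steiger
#' comparisons (two-tailed, unadjusted), and returns a typed report.
#'
#' @param cohort Cohort `data.frame` (one row per subject).
#' @param spec A [battery_spec()].
#' @return A `battery_report`: `correlations` (data.frame with `brain`,
#'   `behavior`, `partial`, `r`, `n`, `df`, `statistic`, `p_raw`, `p_fdr`,
#'   `significant`), `comparisons` (data.frame with `label`, `r12`, `r13`,
#'   `r23`, `z`, `p`), `q`, and `family` (the family definition used).
#' @export
run_battery <- function(cohort, spec = battery_spec()) {
  need <- c(spec$fa_columns, spec$strength_columns, spec$behavior_columns,
            spec$covariate)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  cohort <- cohort[complete.cases(cohort[, need]), , drop = FALSE]
  rows <- list()
  for (bc in spec$behavior_columns) {
    for (fc in spec$fa_columns) {
      cr <- pearson_one_tailed(cohort[[fc]], cohort[[bc]])
      rows[[length(rows) + 1L]] <- data.frame(
        brain = fc, behavior = bc, partial = FALSE, r = cr$r, n = cr$n,
        df = cr$df, statistic = cr$t_or_z, p_raw = cr$p_raw)
    }
    for (sc in spec$strength_columns) {
      cr <- if (is.null(spec$covariate))
        pearson_one_tailed(cohort[[sc]], cohort[[bc]])
      else
        partial_corr_one_tailed(cohort[[sc]], cohort[[bc]],
                                cohort[[spec$covariate]])
      rows[[length(rows) + 1L]] <- data.frame(
        brain = sc, behavior = bc, partial = !is.null(spec$covariate),
        r = cr$r, n = cr$n, df = cr$df, statistic = cr$t_or_z,
        p_raw = cr$p_raw)
    }
  }
  correlations <- do.call(rbind, rows)
  correlations$p_fdr <- bh_fdr(correlations$p_raw)
  correlations$significant <- correlations$p_fdr <= spec$q
  comparisons <- do.call(rbind, lapply(spec$comparisons, function(cp) {
    r12 <- cor(cohort[[cp$shared]], cohort[[cp$a]])
    r13 <- cor(cohort[[cp$shared]], cohort[[cp$b]])
    r23 <- cor(cohort[[cp$a]], cohort[[cp$b]])
    st <- steiger_z(r12, r13, r23, nrow(cohort))
    data.frame(label = cp$label, r12 = r12, r13 = r13, r23 = r23,
               z = st$z, p = st$p_two_tailed)
  }))
  structure(list(correlations = correlations, comparisons = comparisons,
                 q = spec$q,
                 family = "all one-tailed brain-behavior correlations in this run"),
            class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("Brain-behavior battery: %d correlations (FDR q = %g, family: %s)\n",
              nrow(x$correlations), x$q, x$family))
  df <- x$correlations
  df$r <- round(df$r, 3); df$p_raw <- signif(df$p_raw, 3)
  df$p_fdr <- signif(df$p_fdr, 3); df$statistic <- round(df$statistic, 3)
  print(df, row.names = FALSE)
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("Dependent-correlation comparisons (two-tailed, unadjusted):\n")
    cmp <- x$comparisons
    cmp$z <- round(cmp$z, 3); cmp$p <- signif(cmp$p, 3)
    cmp$r12 <- round(cmp$r12, 3); cmp$r13 <- round(cmp$r13, 3)
    cmp$r23 <- round(cmp$r23, 3)
    print(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' Write a battery report as TSV (+ JSON)
#'
#' @param report A `battery_report`.
#' @param tsv_path Path for the correlation table; the comparison table goes
#'   next to it with suffix `_comparisons.tsv`.
#' @param json_path Optional path for a JSON rendering of the full report.
#' @export
write_battery_report <- function(report, tsv_path, json_path = NULL) {
  write.table(report$correlations, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$comparisons,
              sub("\\.tsv$", "_comparisons.tsv", tsv_path), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(correlations = report$correlations,
                              comparisons = report$comparisons,
                              q = report$q, family = report$family),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
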