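# Behavioral scoring for value-directed remembering lists: per-list point
# scores, the Selectivity Index, and per-subject summaries.

#' Define a value-directed remembering study design
#'
#' The default design is the standard task: five studied lists of 24 unique
#' words each, half assigned a high point value (10, 11 or 12) and half a low
#' point value (1, 2 or 3), with each value appearing equally often within a
#' list. The mean point value of the default list is exactly 6.5.
#'
#' @param n_lists Number of scored lists per subject.
#' @param words_per_list Words studied per list.
#' @param high_values Point values used for high-value words.
#' @param low_values Point values used for low-value words.
#' @param n_high_per_list,n_low_per_list Words of each class per list. Must
#'   be divisible by the number of distinct values in the class.
#' @return An object of class `vdr_design` with the per-list value vector in
#'   `$list_values` (order is arbitrary; scoring is order-invariant).
#' @export
study_design <- function(n_lists = 5L, words_per_list = 24L,
                         high_values = c(10, 11, 12),
                         low_values = c(1, 2, 3),
                         n_high_per_list = 12L, n_low_per_list = 12L) {
  if (n_high_per_list + n_low_per_list != words_per_list)
    stop("n_high_per_list + n_low_per_list must equal words_per_list")
  if (min(high_values) <= max(low_values))
    stop("every high value must exceed every low value")
  if (n_high_per_list %% length(high_values) != 0 ||
      n_low_per_list %% length(low_values) != 0)
    stop("per-class word counts must be divisible by the number of values")
  list_values <- c(rep(high_values, n_high_per_list / length(high_values)),
                   rep(low_values, n_low_per_list / length(low_values)))
  structure(list(
    n_lists = as.integer(n_lists),
    words_per_list = as.integer(words_per_list),
    high_values = high_values, low_values = low_values,
    n_high_per_list = as.integer(n_high_per_list),
    n_low_per_list = as.integer(n_low_per_list),
    list_values = list_values
  ), class = "vdr_design")
}

#' @export
print.vdr_design <- function(x, ...) {
  cat(sprintf("Value-directed remembering design: %d lists x %d words\n",
              x$n_lists, x$words_per_list))
  cat(sprintf("  high values {%s} x %d, low values {%s} x %d, mean value %.3g\n",
              paste(x$high_values, collapse = ","), x$n_high_per_list,
              paste(x$low_values, collapse = ","), x$n_low_per_list,
              mean(x$list_values)))
  invisible(x)
}

#' Construct a single-list recall record
#'
#' @param values Point value of each studied word, in study order.
#' @param recalled Logical vector (or integer index vector) marking which
#'   studied words were recalled.
#' @return An object of class `recall_record`.
#' @export
recall_record <- function(values, recalled) {
  if (length(values) < 1L) stop("a recall record needs at least one studied word")
  if (!is.logical(recalled)) {
    idx <- as.integer(recalled)
    if (length(idx) && (min(idx) < 1L || max(idx) > length(values)))
      stop("recalled indices outside the studied list")
    recalled <- seq_along(values) %in% idx
  }
  if (length(recalled) != length(values))
    stop("values and recalled must have equal length")
  structure(list(values = as.numeric(values), recalled = recalled),
            class = "recall_record")
}

#' Score one recall list
#'
#' Computes the point-score decomposition used for the Selectivity Index:
#' * `actual`: points earned, the sum of values of the recalled words;
#' * `chance`: points expected had values been assigned at random, i.e. the
#'   mean list value times the number of words recalled;
#' * `ideal`: the best achievable score for that many recalled words, the sum
#'   of the largest `n_recalled` values on the list.
#'
#' The Selectivity Index `(actual - chance) / (ideal - chance)` is attached
#' when defined; it is `NA` when `ideal == chance` (zero recall, or recall of
#' the entire list), because value selectivity is then unobservable.
#'
#' @param record A [recall_record()].
#' @param design Optional [study_design()] used to classify recalled words as
#'   high or low value; defaults to the standard design.
#' @return A `list_score` object with fields `actual`, `chance`, `ideal`,
#'   `n_recalled`, `n_high_recalled`, `n_low_recalled`, `selectivity`.
#' @export
score_list <- function(record, design = study_design()) {
  stopifnot(inherits(record, "recall_record"))
  v <- record$values
  rec <- record$recalled
  n_recalled <- sum(rec)
  actual <- sum(v[rec])
  chance <- mean(v) * n_recalled
  ideal <- sum(sort(v, decreasing = TRUE)[seq_len(n_recalled)])
  hi_cut <- min(design$high_values)
  score <- structure(list(
    actual = actual, chance = chance, ideal = ideal,
    n_recalled = n_recalled,
    n_high_recalled = sum(rec & v >= hi_cut),
    n_low_recalled = sum(rec & v < hi_cut),
    selectivity = NA_real_
  ), class = "list_score")
  if (ideal != chance) score$selectivity <- (actual - chance) / (ideal - chance)
  score
}

#' Selectivity Index of a scored list
#'
#' `(actual - chance) / (ideal - chance)`. Equals 1 exactly when the recalled
#' words are the top-valued `n_recalled` words, 0 for value-insensitive
#' recall, and is negative when low-value words are preferred. Undefined
#' (error) when `ideal == chance`.
#'
#' @param score A `list_score` from [score_list()].
#' @return The Selectivity Index, a dimensionless scalar `<= 1`.
#' @export
selectivity_index <- function(score) {
  stopifnot(inherits(score, "list_score"))
  if (score$ideal == score$chance)
    stop("Selectivity Index undefined: ideal score equals chance score ",
         "(zero recall or full-list recall)")
  (score$actual - score$chance) / (score$ideal - score$chance)
}

#' Summarize a subject's lists
#'
#' Averages per-list scores across a subject's lists: mean number of
#' high-value and low-value words recalled per list, and the mean Selectivity
#' Index. Lists whose Selectivity Index is undefined (zero or full recall)
#' are excluded from the selectivity mean only; recall means always use all
#' lists.
#'
#' @param records A list of [recall_record()]s, one per studied list.
#' @param design A [study_design()].
#' @return A `subject_summary` object: `mean_high_recall`, `mean_low_recall`,
#'   `mean_selectivity` (`NA` if no list had a defined index),
#'   `n_lists_scored`.
#' @export
subject_summary <- function(records, design = study_design()) {
  if (length(records) < 1L) stop("at least one list is required")
  scores <- lapply(records, score_list, design = design)
  sel <- vapply(scores, function(s) s$selectivity, numeric(1))
  structure(list(
    mean_high_recall = mean(vapply(scores, `[[`, numeric(1), "n_high_recalled")),
    mean_low_recall = mean(vapply(scores, `[[`, numeric(1), "n_low_recalled")),
    mean_selectivity = if (all(is.na(sel))) NA_real_ else mean(sel, na.rm = TRUE),
    n_lists_scored = length(scores)
  ), class = "subject_summary")
}

# ---- group-level t tests ---------------------------------------------------

t_from_mean_sd <- function(m, s, n, mu0 = 0) {
  if (s == 0) {
    t <- if (m == mu0) 0 else sign(m - mu0) * Inf
    if (!is.finite(t)) warning("zero variance: t statistic is infinite")
    p <- if (is.finite(t)) 1 else 0
    return(list(t = t, df = n - 1L, p = p))
  }
  t <- (m - mu0) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * pt(-abs(t), df = n - 1))
}

#' Paired t test on per-subject scores
#'
#' Two-tailed paired t test, `t = mean(x - y) / (sd(x - y) / sqrt(n))` with
#' `n - 1` degrees of freedom. When the paired differences have zero variance
#' the statistic is reported as 0 (mean difference zero) or signed infinity,
#' with a warning, rather than erroring, so that simulation sweeps never
#' abort.
#'
#' @param x,y Numeric vectors of equal length (one entry per subject).
#' @return A list with `t`, `df`, `p` (two-tailed).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  t_from_mean_sd(mean(d), sd(d), length(d))
}

#' One-sample t test against a reference value
#'
#' @param x Numeric vector (one entry per subject).
#' @param mu0 Reference value under the null.
#' @return A list with `t`, `df`, `p` (two-tailed).
#' @export
one_sample_t <- function(x, mu0 = 0) {
  stopifnot(length(x) >= 2)
  t_from_mean_sd(mean(x), sd(x), length(x), mu0 = mu0)
}

# ---- behavioral table I/O --------------------------------------------------

#' Read a behavioral trial table
#'
#' Expects a TSV with columns `subject_id`, `list_id`, `word_idx`, `value`,
#' `recalled` (0/1), one row per studied word, and validates it against the
#' design (words per list, admissible values).
#'
#' @param path Path to the TSV file.
#' @param design A [study_design()] to validate against.
#' @return The validated trial `data.frame`.
#' @export
read_recall_tsv <- function(path, design = study_design()) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_recall_table(df, design)
  df
}

validate_recall_table <- function(df, design) {
  need <- c("subject_id", "list_id", "word_idx", "value", "recalled")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$recalled %in% c(0, 1))) stop("recalled must be 0/1")
  ok_values <- c(design$high_values, design$low_values)
  if (!all(df$value %in% ok_values))
    stop("word values outside the design's value sets")
  n_words <- tapply(df$word_idx, interaction(df$subject_id, df$list_id, drop = TRUE), length)
  if (!all(n_words == design$words_per_list))
    stop("every subject x list must have exactly ", design$words_per_list, " words")
  invisible(df)
}

#' Write per-subject behavioral summaries as TSV
#'
#' @param summaries Named list of `subject_summary` objects (names are
#'   subject ids), or the data.frame from [score_cohort_behavior()].
#' @param path Output path.
#' @export
write_summary_tsv <- function(summaries, path) {
  if (!is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(names(summaries), function(id) {
      s <- summaries[[id]]
      data.frame(subject_id = id,
                 mean_high_recall = s$mean_high_recall,
                 mean_low_recall = s$mean_low_recall,
                 mean_selectivity = s$mean_selectivity)
    }))
  }
  write.table(summaries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score a full behavioral trial table
#'
#' Splits a trial table (as read by [read_recall_tsv()] or produced by
#' [simulate_recall()]) by subject and scores every list.
#'
#' @param trials Trial `data.frame` with columns `subject_id`, `list_id`,
#'   `word_idx`, `value`, `recalled`.
#' @param design A [study_design()].
#' @return A `data.frame` with one row per subject: `subject_id`,
#'   `mean_high_recall`, `mean_low_recall`, `mean_selectivity`,
#'   `n_lists_scored`.
#' @export
score_cohort_behavior <- function(trials, design = study_design()) {
  validate_recall_table(trials, design)
  # vectorized over subject x list groups (agrees with subject_summary();
  # the per-list path is kept as the reference implementation)
  g <- interaction(trials$subject_id, trials$list_id, drop = TRUE)
  rec <- trials$recalled == 1
  hi_cut <- min(design$high_values)
  n_rec <- as.vector(rowsum(rec * 1, g))
  actual <- as.vector(rowsum(trials$value * rec, g))
  mean_v <- as.vector(rowsum(trials$value, g)) / as.vector(rowsum(rep(1, nrow(trials)), g))
  chance <- mean_v * n_rec
  # ideal: per group, sum of the n_rec largest values
  ord <- order(g, -trials$value)
  rk <- sequence(tabulate(g))
  sel <- rk <= n_rec[as.integer(g[ord])]
  ideal <- numeric(nlevels(g))
  if (any(sel)) {
    id_sum <- rowsum(trials$value[ord][sel], g[ord][sel])
    ideal[match(rownames(id_sum), levels(g))] <- id_sum
  }
  selv <- ifelse(ideal != chance, (actual - chance) / (ideal - chance),
                 NA_real_)
  n_hi <- as.vector(rowsum((rec & trials$value >= hi_cut) * 1, g))
  n_lo <- as.vector(rowsum((rec & trials$value < hi_cut) * 1, g))
  subj_of_g <- trials$subject_id[match(levels(g), g)]
  ids <- unique(trials$subject_id)
  agg <- function(x, na_rm = FALSE)
    as.vector(tapply(x, factor(subj_of_g, levels = ids), mean,
                     na.rm = na_rm))
  out <- data.frame(
    subject_id = ids,
    mean_high_recall = agg(n_hi),
    mean_low_recall = agg(n_lo),
    mean_selectivity = agg(selv, na_rm = TRUE),
    n_lists_scored = as.vector(table(factor(subj_of_g, levels = ids))))
  out$mean_selectivity[is.nan(out$mean_selectivity)] <- NA_real_
  rownames(out) <- NULL
  out
}
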