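# Synthetic cohort generator: latent subject traits jointly drive recall
# behavior and the phantom imaging parameters, so that end-to-end runs
# reproduce the study's qualitative brain-behavior structure.

#' Effect configuration for the cohort simulator
#'
#' Three standard-normal latent traits per subject drive everything:
#' `general_ability` and `semantic_integrity` shift the recall log-odds
#' intercept, `reward_sensitivity` shifts the value-sensitivity slope.
#' `semantic_integrity` additionally loads on the fronto-temporal bundle
#' coherence (hence its FA), and `reward_sensitivity` on the seed-target
#' bundle coherence (hence its tract strength). A control tract never loads
#' on any trait.
#'
#' Each studied word is recalled independently with probability
#' `plogis(a_i + g_i * z(v))` where `a_i = alpha0 + w_ability * ability +
#' w_semantic * semantic`, `g_i = gamma0 + w_reward * reward`, and `z(v)` is
#' the word's point value standardized over the list's value distribution.
#'
#' Defaults are calibrated so a large cohort reproduces the study's group
#' profile (mean high-value recall near 8.6/12, low-value recall near
#' 3.2/12, mean Selectivity Index near 0.6) and the target population
#' correlations of the analytic surrogates: about 0.7 between bundle-FA
#' surrogate and high-value recall, about 0.5 between tract-strength
#' surrogate and Selectivity Index.
#'
#' @param n_subjects Cohort size (default 19, the study's sample size).
#' @param alpha0 Recall log-odds intercept.
#' @param w_ability,w_semantic Trait weights into the recall intercept.
#' @param gamma0 Baseline value-sensitivity slope (log-odds per SD of value).
#' @param w_reward Trait weight into the value-sensitivity slope.
#' @param fa_loading,fa_noise_sd Loading of `semantic_integrity` on the
#'   bundle-coherence / FA surrogate, and its noise SD.
#' @param ts_loading,ts_noise_sd Loading of `reward_sensitivity` on the
#'   seed-target coherence / tract-strength surrogate, and its noise SD.
#' @param trait_cor 3x3 correlation matrix of the traits (default identity).
#' @param seed Master RNG seed; all stages derive child streams from it.
#' @return An `effect_config` list.
#' @export
effect_config <- function(n_subjects = 19L,
                          alpha0 = -0.04, w_ability = 0.3, w_semantic = 0.8,
                          gamma0 = 1.2, w_reward = 0.45,
                          fa_loading = 1, fa_noise_sd = 0.5,
                          ts_loading = 1, ts_noise_sd = 1.35,
                          trait_cor = diag(3), seed = 1L) {
  if (n_subjects < 4) stop("n_subjects must be >= 4")
  if (fa_noise_sd <= 0 || ts_noise_sd <= 0) stop("noise sds must be > 0")
  trait_cor <- as.matrix(trait_cor)
  if (!isTRUE(all.equal(trait_cor, t(trait_cor))) ||
      any(eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
    stop("trait_cor must be a symmetric positive-definite correlation matrix")
  structure(list(
    n_subjects = as.integer(n_subjects), alpha0 = alpha0,
    w_ability = w_ability, w_semantic = w_semantic,
    gamma0 = gamma0, w_reward = w_reward,
    fa_loading = fa_loading, fa_noise_sd = fa_noise_sd,
    ts_loading = ts_loading, ts_noise_sd = ts_noise_sd,
    trait_cor = trait_cor, seed = as.integer(seed)
  ), class = "effect_config")
}

#' Read / write an effect configuration as YAML
#' @param path YAML file path.
#' @return For the reader, an [effect_config()]; the writer returns `path`.
#' @export
read_effect_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$trait_cor)) y$trait_cor <- matrix(unlist(y$trait_cor), 3, 3)
  do.call(effect_config, y)
}

#' @rdname read_effect_config
#' @param config An [effect_config()].
#' @export
write_effect_config <- function(config, path) {
  y <- unclass(config)
  y$trait_cor <- as.list(as.data.frame(y$trait_cor))
  names(y$trait_cor) <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Draw latent subject traits
#'
#' @param config An [effect_config()].
#' @param seed RNG seed (defaults to the config's master seed).
#' @return A `data.frame` with columns `subject_id`, `general_ability`,
#'   `semantic_integrity`, `reward_sensitivity`.
#' @export
draw_traits <- function(config, seed = config$seed) {
  maybe_set_seed(seed)
  z <- MASS::mvrnorm(config$n_subjects, mu = rep(0, 3), Sigma = config$trait_cor)
  data.frame(subject_id = sprintf("S%03d", seq_len(config$n_subjects)),
             general_ability = z[, 1],
             semantic_integrity = z[, 2],
             reward_sensitivity = z[, 3])
}

#' Simulate recall behavior for a cohort
#'
#' Independent-Bernoulli logistic recall in standardized word value (see
#' [effect_config()]). No list-level capacity constraint is imposed; recall
#' totals vary freely around their subject-specific expectation.
#'
#' @param traits Trait table from [draw_traits()].
#' @param design A [study_design()].
#' @param config An [effect_config()].
#' @param seed RNG seed.
#' @return A trial `data.frame` (`subject_id`, `list_id`, `word_idx`,
#'   `value`, `recalled`) suitable for [score_cohort_behavior()].
#' @export
simulate_recall <- function(traits, design = study_design(), config,
                            seed = NULL) {
  maybe_set_seed(seed)
  v <- design$list_values
  zv <- (v - mean(v)) / sd(v)
  n <- nrow(traits)
  a <- config$alpha0 + config$w_ability * traits$general_ability +
    config$w_semantic * traits$semantic_integrity
  g <- config$gamma0 + config$w_reward * traits$reward_sensitivity
  nw <- design$words_per_list
  nl <- design$n_lists
  # rows: subject x list x word, word fastest
  eta <- rep(a, each = nl * nw) + rep(g, each = nl * nw) * rep(zv, times = n * nl)
  p <- plogis(eta)
  data.frame(
    subject_id = rep(traits$subject_id, each = nl * nw),
    list_id = rep(rep(seq_len(nl), each = nw), times = n),
    word_idx = rep(seq_len(nw), times = n * nl),
    value = rep(v, times = n * nl),
    recalled = as.integer(runif(length(p)) < p)
  )
}

#' Map latent traits to phantom parameters
#'
#' Translates traits into the physical knobs of the diffusion phantom:
#' * `uf_coherence` (0-1): fiber coherence of the fronto-temporal bundle,
#'   increasing in `semantic_integrity`; controls the bundle's radial
#'   diffusivity and hence its ground-truth FA.
#' * `control_coherence` (0-1): coherence of the control bundle, independent
#'   of all traits.
#' * `st_dispersion` (radians): angular dispersion of the seed-target bundle
#'   fibers, decreasing in `reward_sensitivity`; higher dispersion scatters
#'   streamlines and lowers tract strength.
#'
#' Values falling outside their admissible range are clamped with a warning.
#'
#' @param traits Trait table from [draw_traits()].
#' @param config An [effect_config()].
#' @param seed RNG seed for the mapping noise.
#' @return A `data.frame` with `subject_id`, `uf_coherence`,
#'   `control_coherence`, `st_dispersion`.
#' @export
phantom_params_from_traits <- function(traits, config, seed = NULL) {
  maybe_set_seed(seed)
  n <- nrow(traits)
  uf_raw <- 0.62 + 0.10 * (config$fa_loading * traits$semantic_integrity +
                             rnorm(n, 0, config$fa_noise_sd))
  ctrl_raw <- 0.62 + 0.10 * rnorm(n, 0, 1)
  disp_raw <- 0.30 - 0.10 * (config$ts_loading * traits$reward_sensitivity +
                               rnorm(n, 0, config$ts_noise_sd))
  uf <- clamp(uf_raw, 0.05, 0.95)
  ctrl <- clamp(ctrl_raw, 0.05, 0.95)
  disp <- clamp(disp_raw, 0.02, 1.2)
  n_clamped <- sum(uf != uf_raw) + sum(ctrl != ctrl_raw) + sum(disp != disp_raw)
  if (n_clamped > 0)
    warning(n_clamped, " phantom parameter(s) clamped to their admissible range")
  data.frame(subject_id = traits$subject_id,
             uf_coherence = uf, control_coherence = ctrl,
             st_dispersion = disp)
}

#' Simulate a cohort table (behavior-only fast path)
#'
#' Composes [draw_traits()] -> [simulate_recall()] ->
#' [score_cohort_behavior()] and attaches analytic (noise-plus-loading)
#' imaging surrogates, so the full statistical battery can run without the
#' imaging stages. Surrogate columns:
#' `fa_uf_left`, `fa_uf_right` (both loading on `semantic_integrity` with
#' independent noise, so left and right correlate through the shared trait),
#' `fa_control` (pure noise), `ts_nacc_vta` (loading on
#' `reward_sensitivity`), and `target_size` (a trait-independent voxel-count
#' covariate for the partial correlation).
#'
#' @param config An [effect_config()].
#' @param design A [study_design()].
#' @param surrogates Attach analytic imaging surrogates (default `TRUE`).
#' @param keep_traits Attach the latent trait columns (for recovery tests).
#' @return A cohort `data.frame`, one row per subject.
#' @export
simulate_cohort <- function(config = effect_config(),
                            design = study_design(),
                            surrogates = TRUE, keep_traits = FALSE) {
  seeds <- child_seeds(config$seed, 3L)
  traits <- draw_traits(config, seed = seeds[1])
  trials <- simulate_recall(traits, design, config, seed = seeds[2])
  cohort <- score_cohort_behavior(trials, design)
  if (surrogates) {
    maybe_set_seed(seeds[3])
    n <- nrow(traits)
    cohort$fa_uf_left <- config$fa_loading * traits$semantic_integrity +
      rnorm(n, 0, config$fa_noise_sd)
    cohort$fa_uf_right <- config$fa_loading * traits$semantic_integrity +
      rnorm(n, 0, config$fa_noise_sd)
    cohort$fa_control <- rnorm(n)
    cohort$ts_nacc_vta <- config$ts_loading * traits$reward_sensitivity +
      rnorm(n, 0, config$ts_noise_sd)
    cohort$target_size <- round(runif(n, 40, 80))
  }
  if (keep_traits) {
    cohort$general_ability <- traits$general_ability
    cohort$semantic_integrity <- traits$semantic_integrity
    cohort$reward_sensitivity <- traits$reward_sensitivity
  }
  cohort
}

#' Write a cohort table as TSV
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
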