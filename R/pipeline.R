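# End-to-end orchestration: simulate cohort -> phantoms -> FA / tract
# strength -> correlation battery -> report.

#' Assemble a full-run configuration
#'
#' @param effect An [effect_config()].
#' @param layout A [default_phantom_layout()] (or compatible).
#' @param tracking A [tracking_params()]. The default here uses 500 samples
#'   per seed voxel to keep desk-scale runs quick; raise it towards the
#'   tracker's 5000 default for tighter strength estimates.
#' @param battery A [battery_spec()]; `NULL` derives one from the cohort
#'   columns at run time.
#' @param imaging Run the imaging stages (`FALSE` = behavior-only fast path
#'   with analytic surrogates).
#' @param noise_sd Rician noise SD for the phantom DWI.
#' @param seed Global master seed; every stage derives a child stream.
#' @return A `run_config`.
#' @export
run_config <- function(effect = effect_config(),
                       layout = default_phantom_layout(),
                       tracking = tracking_params(samples_per_seed_voxel = 500L),
                       battery = NULL, imaging = TRUE,
                       noise_sd = 1000 / 30, seed = 1L) {
  structure(list(effect = effect, layout = layout, tracking = tracking,
                 battery = battery, imaging = imaging, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "run_config")
}

log_stage <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Stages: (1) simulate the cohort's behavior from latent traits; (2) map
#' traits to phantom parameters; (3) per subject, build the diffusion
#' phantom, fit the FA map, extract mean FA in the thresholded atlas masks
#' (the fronto-temporal bundle, the occipito-frontal corridor with and
#' without the overlap excluded, and the control bundle) and measure
#' seed-to-target tract strength; (4) run the correlation battery; (5)
#' write the cohort TSV, battery report, log and config echo into
#' `out_dir`. With `imaging = FALSE` the imaging stages are skipped and the
#' battery runs on the analytic surrogates.
#'
#' The per-subject target ROI is jittered by one voxel so the target-size
#' covariate of the partial correlation is non-degenerate across subjects.
#'
#' @param config A [run_config()].
#' @param out_dir Writable output directory (created if missing).
#' @param write_nifti Also write each subject's FA map as NIfTI.
#' @return Invisibly, a list with `cohort`, `report`, and `out_dir`.
#' @export
run_full <- function(config = run_config(), out_dir, write_nifti = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("# run seed: %d\n", config$seed), file = log_path)
  seeds <- child_seeds(config$seed, 4L)
  eff <- config$effect
  eff$seed <- seeds[1]

  log_stage(log_path, "stage cohort: n_subjects=%d seed=%d",
            eff$n_subjects, eff$seed)
  cohort <- tryCatch(
    simulate_cohort(eff, surrogates = !config$imaging, keep_traits = TRUE),
    error = function(e) stop("stage 'cohort' failed: ",
                             conditionMessage(e)))

  if (config$imaging) {
    traits <- data.frame(subject_id = cohort$subject_id,
                         general_ability = cohort$general_ability,
                         semantic_integrity = cohort$semantic_integrity,
                         reward_sensitivity = cohort$reward_sensitivity)
    pars <- tryCatch(
      phantom_params_from_traits(traits, eff, seed = seeds[2]),
      error = function(e) stop("stage 'phantom-params' failed: ",
                               conditionMessage(e)))
    sub_seeds <- child_seeds(seeds[3], 3L * nrow(cohort))
    log_stage(log_path, "stage imaging: %d subjects, grid %s, %d samples/voxel",
              nrow(cohort), paste(config$layout$grid_dim, collapse = "x"),
              config$tracking$samples_per_seed_voxel)
    img <- lapply(seq_len(nrow(cohort)), function(i) {
      ph <- build_phantom(config$layout, pars[i, ],
                          noise_sd = config$noise_sd,
                          seed = sub_seeds[3 * i - 2])
      fa <- fa_map(ph$dwi)
      m_uf <- threshold_mask(ph$masks$uf, 0.10)
      m_ifof <- threshold_mask(ph$masks$ifof, 0.10)
      m_ctl <- threshold_mask(ph$masks$control, 0.10)
      # jitter the target ROI by up to one voxel per subject so its size
      # varies across the cohort (covariate for the partial correlation)
      set.seed(sub_seeds[3 * i - 1])
      lay <- config$layout
      jitter <- runif(3, -1, 1)
      tgt <- sphere_mask(lay$grid_dim, lay$target_center + jitter,
                         lay$target_radius)
      model <- orientation_model_from_fibers(ph$fibers, ph$fa_true)
      ts <- count_hits(threshold_mask(ph$masks$seed, 0.5), tgt, model,
                       config$tracking, seed = sub_seeds[3 * i])
      if (write_nifti)
        write_volume_nifti(fa, file.path(out_dir,
                                         sprintf("%s_fa.nii.gz",
                                                 cohort$subject_id[i])),
                           lay$voxel_size)
      data.frame(
        fa_uf = mean_fa(fa, m_uf, "uf", 0.10)$mean_fa,
        fa_ifof = mean_fa(fa, m_ifof, "ifof", 0.10)$mean_fa,
        fa_ifof_excl = mean_fa(fa, exclusive_mask(m_ifof, m_uf),
                               "ifof_exclusive", 0.10)$mean_fa,
        fa_control = mean_fa(fa, m_ctl, "control", 0.10)$mean_fa,
        ts_nacc_vta = ts$strength,
        target_size = ts$target_roi_size)
    })
    cohort <- cbind(cohort, do.call(rbind, img))
    spec <- config$battery %||% battery_spec(
      fa_columns = c("fa_uf", "fa_ifof", "fa_ifof_excl", "fa_control"),
      strength_columns = "ts_nacc_vta", covariate = "target_size",
      comparisons = NULL)
  } else {
    log_stage(log_path, "stage imaging: skipped (behavior-only mode)")
    spec <- config$battery %||% battery_spec()
  }

  log_stage(log_path, "stage battery: %d FA cols + %d strength cols x %d behaviors",
            length(spec$fa_columns), length(spec$strength_columns),
            length(spec$behavior_columns))
  report <- tryCatch(run_battery(cohort, spec),
                     error = function(e) stop("stage 'battery' failed: ",
                                              conditionMessage(e)))

  cohort_out <- cohort[, setdiff(names(cohort),
                                 c("general_ability", "semantic_integrity",
                                   "reward_sensitivity"))]
  write_cohort_tsv(cohort_out, file.path(out_dir, "cohort.tsv"))
  write_battery_report(report, file.path(out_dir, "battery.tsv"),
                       file.path(out_dir, "battery.json"))
  prov <- list(seed = config$seed,
               n_subjects = eff$n_subjects,
               imaging = config$imaging,
               grid_dim = config$layout$grid_dim,
               samples_per_seed_voxel = config$tracking$samples_per_seed_voxel,
               r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("vdrdti")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "done: outputs in %s", out_dir)
  invisible(list(cohort = cohort, report = report, out_dir = out_dir))
}

#' Generate small packaged fixtures for tests and examples
#'
#' Writes (a) the worked-example recall table — a standard 24-word list on
#' which exactly the four words valued 12, 10, 11, 12 were recalled — as
#' TSV, (b) a small noise-free phantom's ground-truth FA map as NIfTI with
#' its bval/bvec scheme, and (c) a minimal 4-subject behavior-only cohort
#' TSV (four is the smallest admissible cohort). All
#' regeneration is deterministic under the packaged seed.
#'
#' @param dir Output directory.
#' @param size `"tiny"` (16^3 phantom grid) or `"small"` (24^3).
#' @param seed RNG seed.
#' @return Invisibly, the vector of written paths.
#' @export
make_fixtures <- function(dir, size = c("tiny", "small"), seed = 42L) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- study_design()
  # worked example: recall exactly one word of value 10, one of 11, two of 12
  v <- design$list_values
  rec_idx <- c(which(v == 12)[1:2], which(v == 10)[1], which(v == 11)[1])
  trials <- data.frame(subject_id = "example", list_id = 1L,
                       word_idx = seq_along(v), value = v,
                       recalled = as.integer(seq_along(v) %in% rec_idx))
  p1 <- file.path(dir, "worked_example_trials.tsv")
  write.table(trials, p1, sep = "\t", quote = FALSE, row.names = FALSE)

  gd <- if (size == "tiny") c(16L, 16L, 16L) else c(24L, 24L, 24L)
  ph <- build_phantom(default_phantom_layout(gd), noise_sd = 0, seed = seed)
  p2 <- file.path(dir, "phantom_fa_true.nii.gz")
  write_volume_nifti(ph$fa_true, p2, ph$layout$voxel_size)
  p3 <- file.path(dir, "phantom.bval"); p4 <- file.path(dir, "phantom.bvec")
  write_bval_bvec(ph$dwi$gtab, p3, p4)

  cfg <- effect_config(n_subjects = 4L, seed = seed)
  cohort <- simulate_cohort(cfg)
  p5 <- file.path(dir, "mini_cohort.tsv")
  write_cohort_tsv(cohort, p5)
  invisible(c(p1, p2, p3, p4, p5))
}
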