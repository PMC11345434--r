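#' Default pipeline configuration
#'
#' All analysis knobs exposed with their conventional values: lag `tau`
#' 0.02 s, narrowband 0.5-2 Hz, display threshold 0.03 for mean effective
#' connectivity, 0.0005 for directional differences, 0.075 for laterality
#' differences, density 0.087 for the density-matched functional-connectivity
#' threshold, and colour cap 0.14 for plots.
#'
#' @param cohort_dir directory of per-participant series written by
#'   [write_region_ts()] (one `<participant>.tsv` + `.yaml` each); `NULL` to
#'   generate a synthetic demo cohort instead.
#' @param region_table path to a region table TSV, or `NULL` for the packaged
#'   default.
#' @param out_dir output directory for artifacts.
#' @param tau lag in seconds.
#' @param band frequency band (Hz) for intrinsic-frequency estimation.
#' @param thresholds named list: `ec`, `diff`, `laterality`, `fc_density`,
#'   `colour_cap`.
#' @param a,G,beta oscillator working point used for the fits.
#' @param fit a [fit_config()].
#' @param synth settings for the demo cohort when `cohort_dir` is `NULL`:
#'   a list with `n_participants`, `n_trials`, `samples_per_trial`, `dt`,
#'   `participant_jitter`, `ff_strength`, `fb_ratio`, `p_link` and `regions`
#'   (`"contrast"`: the regions entering the preplanned contrasts plus V1/V2,
#'   both hemispheres; `"all"`: the full packaged table). Missing entries
#'   fall back to the defaults.
#' @param seed base seed.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(cohort_dir = NULL, region_table = NULL,
                            out_dir = tempfile("hopfec_run_"), tau = 0.02,
                            band = c(0.5, 2),
                            thresholds = list(ec = 0.03, diff = 5e-4,
                                              laterality = 0.075,
                                              fc_density = 0.087,
                                              colour_cap = 0.14),
                            a = -5, G = 150, beta = 0.02,
                            fit = fit_config(),
                            synth = list(), seed = 1) {
  synth_default <- list(n_participants = 21, n_trials = 8,
                        samples_per_trial = 2700, dt = 1e-3,
                        participant_jitter = 0.1, ff_strength = 0.05,
                        fb_ratio = 0.3, p_link = 0.5, regions = "contrast")
  synth <- utils::modifyList(synth_default, as.list(synth))
  structure(list(cohort_dir = cohort_dir, region_table = region_table,
                 out_dir = out_dir, tau = tau, band = band,
                 thresholds = thresholds, a = a, G = G, beta = beta,
                 fit = fit, synth = synth, seed = seed),
            class = "pipeline_config")
}

# internal: regions entering the preplanned contrasts, plus the V1/V2 input
# stages so the demo hierarchy starts at the bottom of the visual system
contrast_region_names <- function() {
  unique(c("V1", "V2",
           unlist(lapply(preplanned_contrasts(),
                         function(ct) c(ct$source, ct$target)))))
}

# internal: demo ground truth over the packaged region table — one hierarchy
# per hemisphere with the region groups as levels, no cross-hemisphere links.
demo_ground_truth <- function(table, ff_strength, fb_ratio, p_link, seed) {
  labs <- region_labels(table)
  n <- length(labs)
  C <- matrix(0, n, n, dimnames = list(labs, labs))
  lev <- table$group
  set.seed(seed)
  for (h in c("L", "R")) {
    sel <- which(table$hemisphere == h)
    for (k in seq_len(max(lev, na.rm = TRUE) - 1)) {
      senders <- sel[lev[sel] == k]
      receivers <- sel[lev[sel] == k + 1]
      for (j in senders) for (i in receivers) {
        if (runif(1) < p_link) {
          C[i, j] <- ff_strength
          C[j, i] <- ff_strength * fb_ratio
        }
      }
    }
  }
  coupling_matrix(C, labs)
}

# internal: read a cohort directory written with write_region_ts()
read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0)
    stop("no .tsv series found in cohort directory ", dir, call. = FALSE)
  lapply(files, read_region_ts)
}

#' Run the end-to-end effective-connectivity pipeline
#'
#' Workflow: load (or synthesise) the cohort of per-participant series;
#' estimate intrinsic frequencies in the band; compute per-participant FC and
#' lagged FS and their cross-participant average; fit the group-level
#' effective connectivity and one fit per participant; derive the symmetrised
#' mean, directional asymmetry, thresholded and density-matched views and the
#' right-minus-left laterality difference; run the six preplanned directional
#' contrasts on the per-participant fits; write everything (TSV matrices,
#' contrast table, YAML manifest) to `config$out_dir`.
#'
#' Configuration is validated before any compute (in particular `tau` must be
#' an integer multiple of the sampling interval). On a stage failure the
#' partial outputs are retained and the manifest records the failed stage.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file with the same
#'   fields).
#' @return Invisibly, a list with the output directory, the contrast table,
#'   the group fit and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg_list)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = list(tau = config$tau, band = config$band,
                                 thresholds = config$thresholds,
                                 a = config$a, G = config$G,
                                 beta = config$beta, seed = config$seed),
                   stages = list())
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    write_manifest(manifest, file.path(out, "manifest.yaml"))
    file.create(file.path(out, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) fail(name, e))
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }

  table <- stage("region_table", {
    tab <- if (is.null(config$region_table)) load_region_table()
           else load_region_table(config$region_table)
    if (is.null(config$cohort_dir) &&
        identical(config$synth$regions, "contrast")) {
      tab <- tab[tab$name %in% contrast_region_names(), ]
      tab <- tab[order(tab$hemisphere, tab$group, tab$name), ]
      tab$index <- seq_len(nrow(tab))
    }
    tab
  })

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) {
      read_cohort_dir(config$cohort_dir)
    } else {
      s <- config$synth
      c_true <- demo_ground_truth(table, s$ff_strength, s$fb_ratio, s$p_link,
                                  config$seed)
      set.seed(config$seed)
      params <- oscillator_params(
        a = config$a, f = runif(nrow(c_true), config$band[1], config$band[2]),
        G = config$G, beta = config$beta, region_ids = rownames(c_true))
      write_matrix_tsv(c_true, file.path(out, "ground_truth.tsv"))
      generate_cohort(c_true, params,
                      cohort_spec(n_participants = s$n_participants,
                                  n_trials = s$n_trials,
                                  samples_per_trial = s$samples_per_trial,
                                  dt = s$dt,
                                  participant_jitter = s$participant_jitter,
                                  seed = config$seed))
    }
  })

  stage("validate", {
    dt <- cohort[[1]]$dt
    L <- config$tau / dt
    if (abs(L - round(L)) > 1e-9 || round(L) < 1)
      stop("tau = ", config$tau, " s is not a positive integer multiple of ",
           "dt = ", dt, " s")
    labs <- cohort[[1]]$region_ids
    if (!setequal(labs, region_labels(table)))
      stop("cohort region ids do not match the region table")
    invisible(NULL)
  })

  freqs <- stage("intrinsic_frequencies",
                 estimate_intrinsic_frequencies(cohort, config$band))

  moments <- stage("moments", {
    per <- lapply(cohort, empirical_moments, tau = config$tau)
    avg <- average_moments(per)
    write_matrix_tsv(avg$fc, file.path(out, "fc_group.tsv"))
    write_matrix_tsv(avg$fs, file.path(out, "fs_group.tsv"))
    yaml::write_yaml(list(tau = avg$tau, dt = avg$dt,
                          n_samples = avg$n_samples,
                          n_participants = length(per)),
                     file.path(out, "moments.yaml"))
    list(per = per, avg = avg)
  })

  params <- oscillator_params(a = config$a, f = unname(freqs), G = config$G,
                              beta = config$beta,
                              region_ids = cohort[[1]]$region_ids)

  group_fit <- stage("group_fit", {
    fit <- fit_ec(moments$avg, params, config$fit)
    write_matrix_tsv(fit$c_hat, file.path(out, "ec_group.tsv"))
    fit
  })

  participant_fits <- stage("participant_fits",
                            lapply(moments$per, fit_ec, params = params,
                                   cfg = config$fit))

  stage("matrices", {
    thr <- config$thresholds
    ec <- group_fit$c_hat
    mean_ec <- symmetrized_mean(ec)
    diff_ec <- asymmetry(ec)
    write_matrix_tsv(apply_display_threshold(mean_ec, thr$ec)$values,
                     file.path(out, "ec_mean_thresholded.tsv"))
    write_matrix_tsv(apply_display_threshold(diff_ec, thr$diff)$values,
                     file.path(out, "ec_asymmetry_thresholded.tsv"))
    fc <- moments$avg$fc
    dmt <- density_matched_threshold(fc, thr$fc_density)
    write_matrix_tsv(apply_display_threshold(fc, dmt$threshold)$values,
                     file.path(out, "fc_density_matched.tsv"))
    lat <- laterality_difference(fc, table)
    write_matrix_tsv(apply_display_threshold(lat, thr$laterality)$values,
                     file.path(out, "fc_laterality_thresholded.tsv"))
    manifest$config$fc_threshold <- dmt$threshold
    invisible(NULL)
  })

  contrast_table <- stage("contrasts", {
    ecs <- lapply(participant_fits, `[[`, "c_hat")
    tab <- run_directional_contrasts(ecs)
    write.table(tab, file.path(out, "contrasts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })

  reliability <- stage("reliability", {
    ecs <- lapply(participant_fits, `[[`, "c_hat")
    if (length(ecs) >= 4)
      as.numeric(split_half_reliability(ecs, seed = config$seed))
    else NA_real_
  })
  manifest$split_half_r <- reliability

  write_manifest(manifest, file.path(out, "manifest.yaml"))
  invisible(list(out_dir = out, contrasts = contrast_table,
                 group_fit = group_fit, manifest = manifest,
                 participant_fits = participant_fits))
}
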