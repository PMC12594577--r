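# Pipeline entry points. cmd_simulate() and cmd_analyze() are the
# programmatic equivalents of the `simulate` / `analyze` CLI subcommands
# (see inst/cli/codavowel.R); every stage writes plain CSV/JSON so each
# figure or table is regenerable from stage outputs alone.

#' Simulate an annotated dataset to disk
#'
#' @param outdir output directory (created).
#' @param config [synthetic_config()] list, or a path to a JSON file with the
#'   same fields.
#' @param seed integer seed; the run is a pure function of (config, seed).
#' @return invisible list of output paths (WAV, annotations, movement, truth,
#'   manifest).
#' @export
cmd_simulate <- function(outdir, config = synthetic_config(), seed = 1L) {
  if (is.character(config)) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    base <- synthetic_config()
    base[names(raw)] <- raw
    config <- base
  }
  if (sum(config$n_codas_per_whale) < 1) stop("config requests zero codas")
  ds <- synthesize_dataset(config, seed, outdir = outdir)
  cv_log("INFO", "simulated ", length(ds$codas), " codas -> ", outdir)
  invisible(ds$paths)
}

#' Run the full analysis pipeline
#'
#' Stages: exclusion filter -> per-click Welch spectra + a/i labels +
#' mismatch histogram -> formant hyperparameter grid + per-whale report ->
#' trajectory statistics + GMM/BIC -> movement correlation -> per-stage CSVs
#' and a run manifest under `outdir`. If a truth CSV from the simulator is
#' present next to the annotations, a truth-recovery summary is added.
#'
#' @param wav_path recording (WAV).
#' @param annotations_path click-annotation CSV ([read_annotations()] format).
#' @param outdir output directory.
#' @param movement_path optional movement CSV; when missing the correlation
#'   stage is skipped with a warning.
#' @param cfg an [analysis_config()].
#' @param stages character vector to restrict stages; default all of
#'   c("click-spectra", "formants", "trajectories", "context").
#' @param seed seed for the stochastic stages (GMM restarts).
#' @return invisible list of stage results.
#' @export
cmd_analyze <- function(wav_path, annotations_path, outdir,
                        movement_path = NULL, cfg = analysis_config(),
                        stages = c("click-spectra", "formants",
                                   "trajectories", "context"),
                        seed = cfg$seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rec <- read_recording(wav_path)
  codas <- read_annotations(annotations_path)
  res <- list()
  outputs <- list()

  flt <- filter_codas(codas, cfg$unknown_whale_ids, cfg$min_codas_per_whale)
  if (nrow(flt$reasons)) {
    utils::write.csv(flt$reasons, file.path(outdir, "exclusions.csv"),
                     row.names = FALSE)
    outputs$exclusions <- "exclusions.csv"
  }
  codas <- flt$kept
  if (!length(codas)) stop("stage filter: no codas left after exclusions")
  res$filter <- flt

  if ("click-spectra" %in% stages) {
    cs <- tryCatch(analyze_click_spectra(rec, codas, cfg),
                   error = function(e) stop("stage click-spectra: ",
                                            conditionMessage(e)))
    utils::write.csv(cs$clicks, file.path(outdir, "clicks.csv"), row.names = FALSE)
    utils::write.csv(cs$codas, file.path(outdir, "coda_labels.csv"), row.names = FALSE)
    ms <- mismatch_summary(cs$majorities)
    utils::write.csv(ms$by_count, file.path(outdir, "mismatch_histogram.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, list(clicks = "clicks.csv", coda_labels = "coda_labels.csv",
                               mismatch = "mismatch_histogram.csv"))
    res$click_spectra <- cs
  }

  if ("formants" %in% stages) {
    hand <- vapply(codas, `[[`, "", "hand_vowel")
    if (any(hand %in% c("a", "i"))) {
      grid_out <- tryCatch(run_hyperparameter_grid(rec, codas, cfg),
                           error = function(e) stop("stage formants: ",
                                                    conditionMessage(e)))
      rep_df <- best_pset_report(grid_out)
      utils::write.csv(grid_out$results, file.path(outdir, "formant_grid.csv"),
                       row.names = FALSE)
      utils::write.csv(rep_df, file.path(outdir, "whale_vowel_report.csv"),
                       row.names = FALSE)
      outputs <- c(outputs, list(formant_grid = "formant_grid.csv",
                                 whale_report = "whale_vowel_report.csv"))
      res$formants <- list(grid = grid_out, report = rep_df)
    } else {
      cv_log("WARN", "no hand vowel labels; formant grid stage skipped")
    }
  }

  if ("trajectories" %in% stages && !is.null(res$click_spectra)) {
    ts <- tryCatch(trajectory_stats(res$click_spectra$clicks),
                   error = function(e) {
                     cv_log("WARN", "stage trajectories skipped: ",
                            conditionMessage(e)); NULL })
    if (!is.null(ts)) {
      utils::write.csv(ts, file.path(outdir, "trajectory_stats.csv"),
                       row.names = FALSE)
      outputs$trajectories <- "trajectory_stats.csv"
      p1 <- ts$c1dist_hz[ts$peak_index == 1]
      if (length(p1) >= 10 * max(cfg$gmm_k_range)) {
        gm <- fit_gmm_bic(p1, cfg$gmm_k_range, cfg$gmm_restarts, seed,
                          cfg$gmm_max_iter, cfg$gmm_tol)
        jsonlite::write_json(
          list(selected_k = gm$selected_k, bic_table = gm$bic_table,
               fits = lapply(gm$fits, function(f)
                 f[c("k", "weights", "means_hz", "variances",
                     "log_likelihood", "bic")])),
          file.path(outdir, "gmm_report.json"), auto_unbox = TRUE, digits = NA,
          pretty = TRUE)
        outputs$gmm <- "gmm_report.json"
        res$gmm <- gm
      } else cv_log("WARN", "too few codas for GMM selection; skipped")
      res$trajectories <- ts
    }
  }

  if ("context" %in% stages) {
    if (!is.null(movement_path) && file.exists(movement_path) &&
        !is.null(res$click_spectra)) {
      mv <- read_movement(movement_path)
      cl <- res$click_spectra$clicks
      cr <- movement_correlation(cl$peak1_hz, cl$peak_time_s, mv)
      utils::write.csv(cr, file.path(outdir, "movement_correlation.csv"),
                       row.names = FALSE)
      outputs$correlation <- "movement_correlation.csv"
      res$correlation <- cr
    } else {
      cv_log("WARN", "movement data unavailable; correlation stage skipped")
    }
  }

  manifest <- list(
    inputs = list(wav = normalizePath(wav_path),
                  annotations = normalizePath(annotations_path),
                  movement = if (!is.null(movement_path)) movement_path),
    input_md5 = list(wav = unname(tools::md5sum(wav_path)),
                     annotations = unname(tools::md5sum(annotations_path))),
    seed = seed, stages = stages,
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("codavowel")),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
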