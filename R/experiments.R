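write_outputs <- function(samples, summary, config, out_dir, prefix) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(samples, file.path(out_dir, paste0(prefix, "_samples.csv")),
            row.names = FALSE)
  cfg <- config
  cfg$config_hash <- substr(paste(
    as.hexmode(utils::head(utf8ToInt(paste(deparse(config),
                                           collapse = "")), 50)),
    collapse = ""), 1, 16)
  jsonlite::write_json(list(config = cfg, summary = summary),
                       file.path(out_dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}

#' Run the responsiveness experiment family
#'
#' Drives [responsiveness_profile()] over the 8 initial-condition codes and
#' 4 signal sets, in the sensitized regime (proteolysis pinned to zero) and
#' optionally also with sampled proteolysis.
#'
#' @param n samples per cell.
#' @param seed RNG seed.
#' @param regimes character subset of `c("f14_zero", "f14_sampled")`.
#' @param out_dir optional output directory for CSV + JSON summaries.
#' @param ... passed to [responsiveness_profile()].
#' @return List with tidy `samples` and per-cell `summary`, both carrying a
#'   `regime` column.
#' @export
run_responsiveness <- function(n = 2000, seed = 1,
                               regimes = c("f14_zero", "f14_sampled"),
                               out_dir = NULL, ...) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  samples <- list(); summaries <- list()
  for (reg in regimes) {
    prof <- responsiveness_profile(n = n, seed = seed,
                                   f14_zero = (reg == "f14_zero"), ...)
    prof$samples$regime <- reg
    prof$summary$regime <- reg
    samples[[reg]] <- prof$samples
    summaries[[reg]] <- prof$summary
  }
  out <- list(samples = do.call(rbind, samples),
              summary = do.call(rbind, summaries))
  rownames(out$samples) <- rownames(out$summary) <- NULL
  write_outputs(out$samples, out$summary,
                list(experiment = "responsiveness", n = n, seed = seed,
                     regimes = regimes),
                out_dir, "responsiveness")
  out
}

#' Run the experimental-observation screening experiment
#'
#' Drives [run_screening()] and summarizes the retained set with
#' [flux_distribution_summary()], including the single-condition retained
#' counts (whose intersection is the jointly retained set).
#'
#' @inheritParams run_screening
#' @param out_dir optional output directory.
#' @return List: `samples`, `distribution` (see
#'   [flux_distribution_summary()]), `retained_counts`.
#' @export
run_screening_experiment <- function(n = 10000, seed = 1,
                                     range_log10 = c(-2, 2),
                                     out_dir = NULL, ...) {
  scr <- run_screening(n = n, seed = seed, range_log10 = range_log10, ...)
  dist <- flux_distribution_summary(scr)
  counts <- c(cond1 = sum(scr$cond1, na.rm = TRUE),
              cond2 = sum(scr$cond2, na.rm = TRUE),
              cond3 = sum(scr$cond3, na.rm = TRUE),
              all = sum(scr$pass_all))
  write_outputs(scr, c(dist[c("n_retained", "mean_ratio",
                              "log10_separation")],
                       as.list(counts)),
                list(experiment = "screening", n = n, seed = seed,
                     range_log10 = range_log10),
                out_dir, "screening")
  list(samples = scr, distribution = dist, retained_counts = counts)
}

#' Run the module-design comparison grid
#'
#' Drives [compare_modules()] over the experiment grid: closed system
#' (slow, fast rates) plus open system (slow, fast) under scenarios 1 and
#' 2 — six cells in total (the closed system has no scenario split).
#'
#' @param n samples per design per cell.
#' @param seed RNG seed.
#' @param cells optional list of [scenario_config()]s; defaults to the
#'   full six-cell grid.
#' @param out_dir optional output directory.
#' @param ... passed to [compare_modules()].
#' @return List with tidy `samples` and `summary`, keyed by cell.
#' @export
run_module_grid <- function(n = 2000, seed = 1, cells = NULL,
                            out_dir = NULL, ...) {
  if (is.null(cells))
    cells <- list(
      closed_slow = scenario_config("closed", "slow"),
      closed_fast = scenario_config("closed", "fast"),
      open_slow_s1 = scenario_config("open", "slow", 1),
      open_slow_s2 = scenario_config("open", "slow", 2),
      open_fast_s1 = scenario_config("open", "fast", 1),
      open_fast_s2 = scenario_config("open", "fast", 2))
  samples <- list(); summaries <- list()
  for (cell in names(cells)) {
    res <- compare_modules(cells[[cell]], n = n, seed = seed, ...)
    res$samples$cell <- cell
    res$summary$cell <- cell
    samples[[cell]] <- res$samples
    summaries[[cell]] <- res$summary
  }
  out <- list(samples = do.call(rbind, samples),
              summary = do.call(rbind, summaries))
  rownames(out$samples) <- rownames(out$summary) <- NULL
  write_outputs(out$samples, out$summary,
                list(experiment = "module_grid", n = n, seed = seed,
                     cells = names(cells)),
                out_dir, "module_grid")
  out
}
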