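#' Configure a multi-block experiment
#'
#' One condition per combination of `variants` and `kappas`; each condition
#' is simulated for `n_blocks` blocks with seeds derived deterministically
#' from `seed`.
#'
#' @param variants Character vector of task variants.
#' @param kappas Numeric vector of cue reliability levels.
#' @param agent An [agent_spec()].
#' @param n_blocks Blocks per condition.
#' @param duration Session length, seconds.
#' @param mean_intervals Per-patch means, seconds.
#' @param seed Base integer seed.
#' @param null_reps Null-model replicates per block.
#' @param window,step Time-course windowing, seconds.
#' @return Object of class `"experiment_config"`.
#' @export
experiment_config <- function(variants = "exponential", kappas = 4,
                              agent = agent_spec("cue_threshold"),
                              n_blocks = 10L, duration = 900,
                              mean_intervals = c(fast = 7, med = 14,
                                                 slow = 21),
                              seed = 1L, null_reps = 1000L,
                              window = 60, step = 10) {
  stopifnot(inherits(agent, "agent_spec"), n_blocks >= 1L)
  structure(list(variants = variants, kappas = kappas, agent = agent,
                 n_blocks = as.integer(n_blocks), duration = duration,
                 mean_intervals = mean_intervals, seed = as.integer(seed),
                 null_reps = as.integer(null_reps), window = window,
                 step = step),
            class = "experiment_config")
}

#' Simulate and analyze a full experiment
#'
#' For every condition (variant x kappa) simulates `n_blocks` sessions,
#' computes per-block metrics, the pooled push-fraction/quality-rank
#' Spearman correlation, and the windowed push-fraction and time-resolved
#' correlation time courses. Fully deterministic given the configuration.
#'
#' If `out_dir` is given, writes per-condition event logs
#' (`events_<cond>.csv`), per-block metrics (`blocks_<cond>.csv`), time
#' courses (`timecourse_<cond>.csv`), and a pooled-statistics JSON
#' (`pooled.json`, requires the `jsonlite` package), refusing to overwrite
#' existing files unless `overwrite = TRUE`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory.
#' @param overwrite Allow overwriting existing outputs?
#' @return Named list (one element per condition) with `logs`, `blocks`
#'   (list of [block_metrics()]), `pooled` (pooled Spearman), `fraction_tc`,
#'   `spearman_tc`, plus the echoed `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  conds <- expand.grid(variant = config$variants, kappa = config$kappas,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(conds))
  names(out) <- sprintf("%s_kappa%g", conds$variant, conds$kappa)
  for (ci in seq_len(nrow(conds))) {
    base <- (config$seed + 100003L * ci) %% 2147483647
    logs <- run_blocks(config$n_blocks, base_seed = base,
                       agent = config$agent,
                       variant = conds$variant[ci],
                       kappa = conds$kappa[ci],
                       duration = config$duration,
                       mean_intervals = config$mean_intervals)
    usable <- vapply(logs, nrow, integer(1)) >= 2L
    if (!all(usable)) {
      warning(sprintf("condition %s: %d block(s) with < 2 pushes skipped",
                      names(out)[ci], sum(!usable)))
    }
    blocks <- lapply(logs[usable], function(l) {
      set.seed((attr(l, "config")$seed + 7L) %% 2147483647)
      block_metrics(l, null_reps = config$null_reps)
    })
    pooled <- if (sum(usable) >= 2L) quality_rank_spearman(logs[usable])
    else NULL
    out[[ci]] <- list(
      logs = logs, blocks = blocks, pooled = pooled,
      fraction_tc = windowed_push_fraction(logs[usable],
                                           config$window, config$step),
      spearman_tc = if (sum(usable) >= 2L) {
        timeresolved_spearman(logs[usable], config$window, config$step)
      } else NULL)
  }
  bundle <- list(conditions = out, config = config)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir, overwrite)
  bundle
}

.write_bundle <- function(bundle, out_dir, overwrite) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  target <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p) && !overwrite) {
      stop("refusing to overwrite existing output ", p,
           " (use overwrite = TRUE)")
    }
    p
  }
  pooled <- list(seed = bundle$config$seed)
  for (cond in names(bundle$conditions)) {
    x <- bundle$conditions[[cond]]
    ev <- target(sprintf("events_%s.csv", cond))
    first <- TRUE
    for (log in x$logs) {
      if (!nrow(log)) next
      tmp <- tempfile()
      write_event_log(log, tmp)
      d <- read.csv(tmp)
      write.table(d, ev, sep = ",", row.names = FALSE, quote = FALSE,
                  col.names = first, append = !first)
      first <- FALSE
    }
    bl <- do.call(rbind, lapply(x$blocks, function(b) {
      data.frame(block_id = b$block_id, n_pushes = b$n_pushes,
                 patch = PATCHES,
                 push_fraction = unname(b$push_fraction),
                 ipi_median = unname(b$ipi_median),
                 stay_norm = unname(b$stay$normalized),
                 return_norm = unname(b$return_time$normalized))
    }))
    write.table(bl, target(sprintf("blocks_%s.csv", cond)), sep = ",",
                row.names = FALSE, quote = FALSE)
    tc <- merge(x$fraction_tc$summary,
                if (!is.null(x$spearman_tc)) x$spearman_tc else
                  data.frame(time = numeric(0)),
                by = "time", all.x = TRUE)
    write.table(tc, target(sprintf("timecourse_%s.csv", cond)), sep = ",",
                row.names = FALSE, quote = FALSE)
    pooled[[cond]] <- if (!is.null(x$pooled)) {
      x$pooled[c("rho", "p", "n")]
    } else NULL
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(pooled, target("pooled.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(out_dir)
}
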