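LOG_COLUMNS <- c("t_s", "patch", "rewarded", "block_id", "variant", "kappa",
                 "mean_interval_s")

#' Write a push-event log to CSV
#'
#' Deterministic column order (`t_s, patch, rewarded, block_id, variant,
#' kappa, mean_interval_s`), timestamps with fixed 6-decimal formatting,
#' newline-terminated. `mean_interval_s` is the mean availability interval of
#' the pressed patch.
#'
#' @param log A `"session_log"`.
#' @param path Output CSV path.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  cfg <- attr(log, "config")
  out <- data.frame(
    t_s = sprintf("%.6f", log$t_s),
    patch = as.character(log$patch),
    rewarded = as.integer(log$rewarded),
    block_id = cfg$block_id,
    variant = cfg$variant,
    kappa = cfg$kappa,
    mean_interval_s = cfg$mean_intervals[as.character(log$patch)])
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a push-event log from CSV
#'
#' Validates the schema (all columns of [write_event_log()] present, known
#' patch labels, strictly increasing timestamps within each block), reporting
#' offending data lines by number. Reconstructs the session configuration
#' from the metadata columns.
#'
#' @param path CSV path.
#' @return A `"session_log"` if the file holds one block, otherwise a named
#'   list of logs (one per `block_id`).
#' @export
read_event_log <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(LOG_COLUMNS, names(raw))
  if (length(missing)) {
    stop("event log schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!raw$patch %in% PATCHES)
  if (length(bad)) {
    stop("unknown patch label(s) at data line(s) ",
         paste(head(bad, 5L), collapse = ", "))
  }
  one_block <- function(d) {
    nonmono <- which(diff(d$t_s) <= 0)
    if (length(nonmono)) {
      stop("timestamps not strictly increasing at data line(s) ",
           paste(head(d$line[nonmono + 1L], 5L), collapse = ", "))
    }
    mi <- tapply(d$mean_interval_s, d$patch, function(v) v[1L])
    means <- c(fast = 7, med = 14, slow = 21)
    means[names(mi)] <- mi
    cfg <- session_config(variant = d$variant[1L], mean_intervals = means,
                          kappa = d$kappa[1L],
                          duration = max(d$t_s), seed = NA_integer_,
                          block_id = d$block_id[1L])
    .as_session_log(d$t_s, d$patch, as.logical(d$rewarded), cfg)
  }
  raw$line <- seq_len(nrow(raw))
  blocks <- split(raw, raw$block_id)
  logs <- lapply(blocks, one_block)
  if (length(logs) == 1L) logs[[1L]] else logs
}
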