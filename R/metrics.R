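#' Fraction of pushes at each patch
#'
#' @param log A `"session_log"` (or data.frame with a `patch` column).
#' @return Named numeric vector (fast, med, slow) summing to 1.
#' @export
push_fraction <- function(log) {
  if (nrow(log) == 0L) stop("push fraction is undefined for an empty log")
  counts <- table(factor(log$patch, levels = PATCHES))
  f <- as.numeric(counts) / nrow(log)
  names(f) <- PATCHES
  f
}

#' Inter-push intervals at one patch (or globally)
#'
#' Per-patch IPIs are the differences between consecutive pushes at the same
#' patch, regardless of intervening pushes elsewhere; `patch = NULL` gives
#' the global (pooled) inter-push intervals.
#'
#' @param log A `"session_log"`.
#' @param patch One of `"fast"`, `"med"`, `"slow"`, or `NULL` for global.
#' @return List with `intervals` (seconds; empty if fewer than 2 pushes) and
#'   `median`.
#' @export
ipi_distribution <- function(log, patch = NULL) {
  t <- if (is.null(patch)) log$t_s else log$t_s[log$patch == patch]
  iv <- if (length(t) >= 2L) diff(t) else numeric(0)
  list(intervals = iv, median = if (length(iv)) median(iv) else NA_real_)
}

#' Two-component separation check for IPI bimodality
#'
#' Splits log-intervals into two clusters (k-means, deterministic quantile
#' initialization) and reports the gap between cluster means relative to the
#' pooled within-cluster spread. Values well above 2 indicate two clearly
#' separated interval regimes (rapid within-patch exploitation vs.
#' disengagement/travel).
#'
#' @param intervals Positive inter-push intervals, seconds.
#' @return List with `separation`, the two cluster means (seconds), and the
#'   mixing proportion of the short cluster.
#' @export
ipi_bimodality <- function(intervals) {
  intervals <- intervals[intervals > 0]
  if (length(intervals) < 10L) stop("need at least 10 positive intervals")
  x <- log(intervals)
  km <- stats::kmeans(x, centers = stats::quantile(x, c(0.1, 0.9)))
  mu <- sort(km$centers[, 1])
  s <- sqrt(km$tot.withinss / (length(x) - 2L))
  list(separation = (mu[2] - mu[1]) / s, means_s = exp(mu),
       prop_short = mean(km$cluster == which.min(km$centers)))
}

#' Patch-transition matrix
#'
#' Counts transitions over consecutive push pairs and normalizes each row.
#' Also reports the conditional probability of switching to the fast patch
#' given a push at a non-fast patch: transitions (med or slow) to fast
#' divided by all transitions out of med and slow.
#'
#' @param log A `"session_log"` with at least 2 pushes.
#' @return Object of class `"transition_matrix"`: list with `P` (3x3, rows =
#'   current patch, columns = next patch), `counts`, and `p_fast_given_notfast`.
#' @export
transition_matrix <- function(log) {
  if (nrow(log) < 2L) stop("need at least 2 pushes")
  from <- factor(log$patch[-nrow(log)], levels = PATCHES)
  to <- factor(log$patch[-1L], levels = PATCHES)
  counts <- table(from, to)
  P <- counts / pmax(rowSums(counts), 1L)
  notfast <- c("med", "slow")
  denom <- sum(counts[notfast, ])
  structure(list(P = unclass(P), counts = unclass(counts),
                 p_fast_given_notfast =
                   if (denom > 0) sum(counts[notfast, "fast"]) / denom
                   else NA_real_),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> P(next | current):\n")
  print(round(x$P, 3))
  cat(sprintf("P(-> fast | not fast) = %.3f\n", x$p_fast_given_notfast))
  invisible(x)
}

#' Segment a log into visits
#'
#' A visit is a maximal run of consecutive pushes at one patch; it begins
#' with the first push following a switch and ends with the last push before
#' switching away. The first and last runs of the session count as visits.
#'
#' @param log A `"session_log"` with at least 1 push.
#' @return `data.frame` with columns `patch`, `t_first`, `t_last`, `n_pushes`.
#' @export
segment_visits <- function(log) {
  if (nrow(log) < 1L) stop("need at least 1 push")
  r <- rle(as.character(log$patch))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(patch = r$values, t_first = log$t_s[starts],
             t_last = log$t_s[ends], n_pushes = r$lengths)
}

#' Stay times per visit
#'
#' Duration between the first and last push of each visit
#' (`t_last - t_first`); single-push visits are retained with stay time 0
#' unless `drop_single = TRUE`.
#'
#' @param visits Output of [segment_visits()].
#' @param drop_single Drop single-push visits?
#' @return `data.frame` with columns `patch`, `stay` (seconds, >= 0).
#' @export
stay_times <- function(visits, drop_single = FALSE) {
  out <- data.frame(patch = visits$patch,
                    stay = visits$t_last - visits$t_first)
  if (drop_single) out <- out[visits$n_pushes > 1L, , drop = FALSE]
  out
}

#' Return times per patch
#'
#' For consecutive visits to the same patch, the gap between the last push
#' before leaving and the first push upon returning.
#'
#' @param visits Output of [segment_visits()].
#' @return `data.frame` with columns `patch`, `return_time` (seconds, > 0);
#'   zero rows for patches never revisited.
#' @export
return_times <- function(visits) {
  out <- lapply(PATCHES, function(p) {
    i <- which(visits$patch == p)
    if (length(i) < 2L) return(NULL)
    data.frame(patch = p,
               return_time = visits$t_first[i[-1L]] -
                 visits$t_last[i[-length(i)]])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(patch = character(0), return_time = numeric(0))
  }
  out
}

# per-patch sums and counts of stay and return times from raw vectors;
# shared by the real-data path and the (hot) null-model loop
.visit_stat_sums <- function(times, labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tf <- times[starts]; tl <- times[ends]
  stay <- tl - tf
  f <- factor(r$values, levels = PATCHES)
  stay_sum <- vapply(split(stay, f), sum, numeric(1))
  stay_n <- tabulate(f, 3L)
  ret_sum <- numeric(3L); ret_n <- integer(3L)
  for (k in seq_along(PATCHES)) {
    i <- which(r$values == PATCHES[k])
    if (length(i) >= 2L) {
      g <- tf[i[-1L]] - tl[i[-length(i)]]
      ret_sum[k] <- sum(g)
      ret_n[k] <- length(g)
    }
  }
  list(stay_sum = stay_sum, stay_n = stay_n,
       ret_sum = ret_sum, ret_n = ret_n)
}

#' Rate-matched null model for stay and return times
#'
#' Generates surrogate event sequences matched to the log in event count and
#' mean push rate: inter-push intervals are exponential at the empirical mean
#' rate and each event receives a uniformly random patch label, removing
#' structured switching while preserving overall event statistics. Stay and
#' return times are computed on each surrogate exactly as on real data and
#' averaged over replicates.
#'
#' @param log A `"session_log"` with at least 2 pushes.
#' @param n_reps Number of surrogate replicates (>= 1; default 1000).
#' @return List with named per-patch `stay` and `return_time` null means
#'   (seconds), `rate` (the empirical mean push rate used), and `n_reps`.
#' @export
null_model <- function(log, n_reps = 1000L) {
  if (n_reps < 1L) stop("`n_reps` must be at least 1")
  n <- nrow(log)
  if (n < 2L) stop("need at least 2 pushes")
  rate <- (n - 1) / (log$t_s[n] - log$t_s[1L])
  stay_sum <- numeric(3L); stay_n <- numeric(3L)
  ret_sum <- numeric(3L); ret_n <- numeric(3L)
  for (rep in seq_len(n_reps)) {
    t <- cumsum(c(0, rexp(n - 1L, rate)))
    lab <- PATCHES[sample.int(3L, n, replace = TRUE)]
    s <- .visit_stat_sums(t, lab)
    stay_sum <- stay_sum + s$stay_sum; stay_n <- stay_n + s$stay_n
    ret_sum <- ret_sum + s$ret_sum; ret_n <- ret_n + s$ret_n
  }
  stay <- stay_sum / pmax(stay_n, 1); stay[stay_n == 0] <- NA_real_
  ret <- ret_sum / pmax(ret_n, 1); ret[ret_n == 0] <- NA_real_
  names(stay) <- names(ret) <- PATCHES
  list(stay = stay, return_time = ret, rate = rate, n_reps = n_reps)
}

#' Normalize an engagement metric by its null-model expectation
#'
#' Elementwise `real / null`. A ratio of 1 means the observed stay or return
#' times are what overall push rate alone predicts; deviations isolate
#' structure attributable to patch-specific engagement and switching.
#'
#' @param real Observed per-patch means (seconds).
#' @param null Null-model per-patch means (seconds, > 0).
#' @return Ratio(s); `NA` (with a warning) where the null mean is not
#'   positive.
#' @export
normalize_metric <- function(real, null) {
  out <- real / null
  bad <- !is.na(null) & null <= 0
  if (any(bad)) {
    warning("null mean not positive; normalized metric undefined there")
    out[bad] <- NA_real_
  }
  out
}

#' Spearman correlation between push fraction and patch quality rank
#'
#' Pools one (fraction, quality-rank) observation per patch per block
#' (`n = 3 * blocks`; quality ranked slow = 1, med = 2, fast = 3) and tests
#' the pooled rank correlation with the two-sided asymptotic approximation.
#'
#' @param blocks A list of `"session_log"` objects, or a numeric matrix of
#'   push fractions with columns `fast`, `med`, `slow` (one row per block).
#' @return List with `rho`, `p`, `n`, and `flagged = TRUE` (with `rho = NA`)
#'   when the fractions are constant so the correlation is undefined.
#' @export
quality_rank_spearman <- function(blocks) {
  fr <- if (is.matrix(blocks)) blocks[, PATCHES, drop = FALSE] else {
    t(vapply(blocks, push_fraction, numeric(3L)))
  }
  if (nrow(fr) < 2L) stop("need at least 2 blocks")
  x <- as.vector(t(fr))
  y <- rep(QUALITY_RANK[PATCHES], nrow(fr))
  if (sd(x) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x), flagged = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       flagged = FALSE)
}

# exact two-sided permutation p for a Spearman correlation on 3 points
.spearman_exact3 <- function(fracs) {
  y <- QUALITY_RANK[PATCHES]
  rho <- suppressWarnings(cor(fracs, y, method = "spearman"))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3L, byrow = TRUE)
  rhos <- apply(perms, 1L, function(pm) {
    suppressWarnings(cor(fracs, y[pm], method = "spearman"))
  })
  c(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

#' Per-block Spearman correlations (exact, 3 observations)
#'
#' With only three patches per block the asymptotic approximation is invalid,
#' so each block's correlation gets an exact permutation p-value over the six
#' orderings of the quality ranks. Note that with 3 observations the smallest
#' attainable two-sided p is 1/3, so per-block "significance" at conventional
#' levels is unattainable by construction.
#'
#' @param blocks As in [quality_rank_spearman()].
#' @return `data.frame` with one row per block: `rho`, `p`.
#' @export
per_block_spearman <- function(blocks) {
  fr <- if (is.matrix(blocks)) blocks[, PATCHES, drop = FALSE] else {
    t(vapply(blocks, push_fraction, numeric(3L)))
  }
  out <- t(apply(fr, 1L, .spearman_exact3))
  data.frame(rho = out[, "rho"], p = out[, "p"])
}

# centered moving average with shrinking windows at the edges
.movavg <- function(x, half_w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_w, 1L)
  hi <- pmin(seq_len(n) + half_w, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Continuous (piecewise-constant) push rate
#'
#' The instantaneous rate on the interval between consecutive pushes `i` and
#' `i + 1` is `1 / (t[i+1] - t[i])`, held constant over that interval. The
#' series is rescaled by the session's time-averaged rate (so a perfectly
#' periodic session has normalized rate 1 throughout) and smoothed with a
#' centered moving-average window.
#'
#' @param log A `"session_log"` with at least 2 pushes.
#' @param window Smoothing window, seconds.
#' @param dt Sampling resolution of the returned series, seconds.
#' @return List with `step` (data.frame `t_start`, `t_end`, `rate`,
#'   `rate_norm`) and `series` (data.frame `time`, `rate_norm`,
#'   `rate_smooth`), plus `mean_rate`.
#' @export
continuous_push_rate <- function(log, window = 60, dt = 1) {
  n <- nrow(log)
  if (n < 2L) stop("need at least 2 pushes")
  t <- log$t_s
  ipi <- diff(t)
  if (any(ipi <= 0)) {
    dt_min <- min(ipi[ipi > 0], dt)
    warning("duplicate timestamps: clipping infinite rates to 1/min spacing")
    ipi[ipi <= 0] <- dt_min
  }
  r <- 1 / ipi
  mean_rate <- (n - 1) / (t[n] - t[1L])
  step <- data.frame(t_start = t[-n], t_end = t[-1L], rate = r,
                     rate_norm = r / mean_rate)
  grid <- seq(t[1L], t[n], by = dt)
  idx <- pmin(findInterval(grid, t), n - 1L)
  series <- data.frame(time = grid, rate_norm = step$rate_norm[idx])
  series$rate_smooth <- .movavg(series$rate_norm,
                                half_w = max(1L, round(window / (2 * dt))))
  list(step = step, series = series, mean_rate = mean_rate)
}

# per-block windowed push fractions on a common session-relative grid;
# returns time vector and blocks x time x patch array (NA where the window
# holds no pushes)
.windowed_fractions <- function(logs, window = 60, step = 10) {
  dur <- max(vapply(logs, function(l) {
    cfg <- attr(l, "config")
    if (!is.null(cfg$duration)) cfg$duration else max(l$t_s)
  }, numeric(1)))
  centers <- seq(window / 2, max(dur - window / 2, window / 2), by = step)
  arr <- array(NA_real_, dim = c(length(logs), length(centers), 3L),
               dimnames = list(NULL, NULL, PATCHES))
  for (b in seq_along(logs)) {
    log <- logs[[b]]
    if (!nrow(log)) next
    pf <- factor(log$patch, levels = PATCHES)
    for (w in seq_along(centers)) {
      inw <- log$t_s >= centers[w] - window / 2 &
        log$t_s < centers[w] + window / 2
      if (!any(inw)) next
      arr[b, w, ] <- tabulate(pf[inw], 3L) / sum(inw)
    }
  }
  list(time = centers, frac = arr)
}

#' Time course of windowed push fraction
#'
#' Per patch, the fraction of pushes falling in a sliding window, averaged
#' across blocks on a common session-relative time grid. Windows containing
#' no pushes are masked (`NA`) and excluded from the across-block mean.
#'
#' @param logs List of `"session_log"` objects (>= 1).
#' @param window Window length, seconds.
#' @param step Grid step, seconds.
#' @return List with `time` (window centers), `frac` (blocks x time x patch
#'   array), and `summary` (data.frame `time`, `patch`, `mean`, `sem`).
#' @export
windowed_push_fraction <- function(logs, window = 60, step = 10) {
  if (length(logs) < 1L) stop("need at least 1 block")
  wf <- .windowed_fractions(logs, window, step)
  summ <- do.call(rbind, lapply(PATCHES, function(p) {
    m <- wf$frac[, , p, drop = FALSE]
    dim(m) <- dim(wf$frac)[1:2]
    data.frame(time = wf$time, patch = p,
               mean = apply(m, 2L, mean, na.rm = TRUE),
               sem = apply(m, 2L, function(v) {
                 v <- v[!is.na(v)]
                 if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
               }))
  }))
  c(wf, list(summary = summ))
}

#' Time-resolved Spearman correlation with patch quality
#'
#' At each grid time, the Spearman correlation between the three windowed
#' push fractions and the quality ranks is computed per block (with 3
#' observations it takes values in -1, -0.5, 0, 0.5, 1) and then averaged
#' across blocks. Masked windows (no pushes, or constant fractions)
#' propagate as `NA` and are dropped from the average.
#'
#' @param logs List of `"session_log"` objects (>= 2).
#' @param window Window length, seconds.
#' @param step Grid step, seconds.
#' @return `data.frame` with `time`, `mean_rho`, `sem`, `n_blocks`.
#' @export
timeresolved_spearman <- function(logs, window = 60, step = 10) {
  if (length(logs) < 2L) stop("need at least 2 blocks")
  wf <- .windowed_fractions(logs, window, step)
  y <- QUALITY_RANK[PATCHES]
  rho <- apply(wf$frac, c(1L, 2L), function(f) {
    if (any(is.na(f)) || sd(f) == 0) NA_real_
    else suppressWarnings(cor(f, y, method = "spearman"))
  })
  data.frame(time = wf$time,
             mean_rho = apply(rho, 2L, mean, na.rm = TRUE),
             sem = apply(rho, 2L, function(v) {
               v <- v[!is.na(v)]
               if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
             }),
             n_blocks = apply(rho, 2L, function(v) sum(!is.na(v))))
}

#' Full per-block analysis
#'
#' Computes the complete per-block summary: push fractions, per-patch IPI
#' medians, the transition matrix, and real, null, and normalized stay and
#' return times.
#'
#' @param log A `"session_log"` with at least 2 pushes.
#' @param null_reps Null-model replicates (see [null_model()]).
#' @return Object of class `"block_metrics"`.
#' @export
block_metrics <- function(log, null_reps = 1000L) {
  visits <- segment_visits(log)
  st <- stay_times(visits)
  rt <- return_times(visits)
  real_stay <- vapply(PATCHES, function(p) {
    v <- st$stay[st$patch == p]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  real_ret <- vapply(PATCHES, function(p) {
    v <- rt$return_time[rt$patch == p]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  null <- null_model(log, n_reps = null_reps)
  ipi_med <- vapply(PATCHES, function(p) ipi_distribution(log, p)$median,
                    numeric(1))
  structure(list(
    block_id = attr(log, "config")$block_id,
    n_pushes = nrow(log),
    push_fraction = push_fraction(log),
    ipi_median = ipi_med,
    transitions = transition_matrix(log),
    stay = list(real = real_stay, null = null$stay,
                normalized = normalize_metric(real_stay, null$stay)),
    return_time = list(real = real_ret, null = null$return_time,
                       normalized = normalize_metric(real_ret,
                                                     null$return_time))),
    class = "block_metrics")
}

#' @export
print.block_metrics <- function(x, ...) {
  cat(sprintf("<block_metrics> block %s, %d pushes\n", x$block_id, x$n_pushes))
  cat("push fraction: ",
      paste(sprintf("%s %.3f", PATCHES, x$push_fraction), collapse = ", "),
      "\n")
  cat("IPI median (s):",
      paste(sprintf("%s %.2f", PATCHES, x$ipi_median), collapse = ", "), "\n")
  cat("normalized stay: ",
      paste(sprintf("%.2f", x$stay$normalized), collapse = ", "),
      " | normalized return: ",
      paste(sprintf("%.2f", x$return_time$normalized), collapse = ", "), "\n")
  invisible(x)
}
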