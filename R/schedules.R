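#' Define the reward-availability interval law of one patch
#'
#' A patch delivers reward according to a variable-interval schedule: after
#' every press a waiting interval is sampled, and reward becomes (and stays)
#' available once that interval has elapsed. Two interval laws are supported:
#'
#' * `"exponential"`: intervals with density \eqn{f(\lambda) = \mu e^{-\mu\lambda}},
#'   mean \eqn{1/\mu}, giving a constant hazard \eqn{h(t) = \mu} (memoryless).
#' * `"gamma"`: intervals with shape `a` (default 10) and rate
#'   \eqn{b = a / \mathrm{mean}}, giving a hazard that increases with elapsed
#'   time, which raises the cost of premature presses.
#'
#' @param variant `"exponential"` or `"gamma"`.
#' @param mean_interval Mean waiting time until availability, seconds (> 0).
#' @param shape Gamma shape parameter `a`; ignored for the exponential law.
#' @return An object of class `"schedule_spec"`: a list with `variant`,
#'   `mean_interval`, and the derived parameters (`rate` for exponential;
#'   `shape` and `rate` for gamma, with `shape / rate == mean_interval`).
#' @examples
#' schedule_spec("exponential", 7)
#' schedule_spec("gamma", 14)
#' @export
schedule_spec <- function(variant = c("exponential", "gamma"), mean_interval,
                          shape = 10) {
  variant <- match.arg(variant)
  if (!is.numeric(mean_interval) || length(mean_interval) != 1L ||
      !is.finite(mean_interval) || mean_interval <= 0) {
    stop("`mean_interval` must be a single positive number (seconds)")
  }
  spec <- list(variant = variant, mean_interval = mean_interval)
  if (variant == "exponential") {
    spec$rate <- 1 / mean_interval
  } else {
    if (!is.numeric(shape) || length(shape) != 1L || shape <= 0) {
      stop("`shape` must be a single positive number")
    }
    spec$shape <- shape
    spec$rate <- shape / mean_interval
  }
  structure(spec, class = "schedule_spec")
}

#' @export
print.schedule_spec <- function(x, ...) {
  cat(sprintf("<schedule_spec> %s, mean interval %.3g s", x$variant,
              x$mean_interval))
  if (x$variant == "gamma") {
    cat(sprintf(" (shape %.3g, rate %.4g /s)", x$shape, x$rate))
  } else {
    cat(sprintf(" (rate %.4g /s)", x$rate))
  }
  cat("\n")
  invisible(x)
}

#' Sample reward-availability intervals from a schedule
#'
#' @param spec A [schedule_spec()].
#' @param n Number of intervals to draw.
#' @return Numeric vector of `n` positive durations (seconds).
#' @examples
#' set.seed(1)
#' mean(sample_interval(schedule_spec("gamma", 7), 1000))
#' @export
sample_interval <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (spec$variant == "exponential") {
    rexp(n, rate = spec$rate)
  } else {
    rgamma(n, shape = spec$shape, rate = spec$rate)
  }
}

#' Hazard rate of reward availability
#'
#' Instantaneous rate at which reward becomes available given that it has not
#' yet, at elapsed time `t` since the last press. Constant (`mu`) for the
#' exponential law; strictly increasing from 0 for the gamma law with
#' shape > 1, approaching the gamma rate parameter as `t` grows.
#'
#' @param spec A [schedule_spec()].
#' @param t Elapsed times in seconds (vectorized, all >= 0).
#' @return Numeric vector of hazard rates (1/seconds).
#' @export
hazard <- function(spec, t) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (any(t < 0)) stop("elapsed time `t` must be nonnegative")
  if (spec$variant == "exponential") {
    return(rep_len(spec$rate, length(t)))
  }
  # f(t) / (1 - F(t)) computed on the log scale for numerical stability
  h <- exp(dgamma(t, shape = spec$shape, rate = spec$rate, log = TRUE) -
             pgamma(t, shape = spec$shape, rate = spec$rate,
                    lower.tail = FALSE, log.p = TRUE))
  h[t == 0] <- if (spec$shape > 1) 0 else spec$rate
  h
}

#' Create the evolving state of one patch
#'
#' A `patch_process` tracks the time of the most recent press `t_last` and the
#' currently sampled availability interval `lambda`. Reward is available at
#' time `now` iff `now - t_last >= lambda`.
#'
#' @param patch_id One of `"fast"`, `"med"`, `"slow"`.
#' @param spec A [schedule_spec()].
#' @param t0 Process start time (treated as the time of a virtual press).
#' @return Object of class `"patch_process"`.
#' @export
patch_process <- function(patch_id, spec, t0 = 0) {
  patch_id <- match.arg(patch_id, PATCHES)
  stopifnot(inherits(spec, "schedule_spec"))
  structure(list(patch_id = patch_id, spec = spec, t_last = t0,
                 lambda = sample_interval(spec, 1L)),
            class = "patch_process")
}

#' @export
print.patch_process <- function(x, ...) {
  cat(sprintf("<patch_process> %s (%s): t_last = %.3f s, lambda = %.3f s\n",
              x$patch_id, x$spec$variant, x$t_last, x$lambda))
  invisible(x)
}

#' Cue signal of one patch at a given time
#'
#' The quantity `X(t)` in `[0, 1]` that the visual stimulus encodes:
#'
#' * exponential variant: the cumulative probability that reward has become
#'   available since the last press, \eqn{X = 1 - e^{-\mu (t - t_i)}} — a
#'   statistic of the patch, not of the active interval;
#' * gamma variant: normalized progression through the currently sampled
#'   interval, \eqn{X = \min((t - t_i)/\lambda_i, 1)} — interval-specific
#'   progress information.
#'
#' Between presses `X` is nondecreasing in `now` for both variants.
#'
#' @param process A [patch_process()].
#' @param now Query time in seconds (must be >= the last press time).
#' @return Cue value in `[0, 1]`.
#' @export
cue_value <- function(process, now) {
  stopifnot(inherits(process, "patch_process"))
  elapsed <- now - process$t_last
  if (elapsed < 0) stop("`now` precedes the most recent press")
  if (process$spec$variant == "exponential") {
    1 - exp(-process$spec$rate * elapsed)
  } else {
    min(elapsed / process$lambda, 1)
  }
}

#' Press the button at a patch
#'
#' Evaluates the press against the active interval — the press is rewarded iff
#' the elapsed time since the previous press is at least the sampled interval
#' `lambda` — then, rewarded or not, resets the patch: a fresh interval is
#' sampled and the press time becomes the new reference time.
#'
#' @param process A [patch_process()].
#' @param now Press time in seconds (must not precede the previous press).
#' @return List with `outcome` (list: `time`, `patch_id`, `rewarded`) and
#'   `process`, the updated patch state.
#' @export
press <- function(process, now) {
  stopifnot(inherits(process, "patch_process"))
  elapsed <- now - process$t_last
  if (elapsed < 0) stop("press time regression: `now` precedes previous press")
  rewarded <- elapsed >= process$lambda
  process$lambda <- sample_interval(process$spec, 1L)
  process$t_last <- now
  list(outcome = list(time = now, patch_id = process$patch_id,
                      rewarded = rewarded),
       process = process)
}

#' Waiting time to availability under premature resets (exponential only)
#'
#' Measures, from the start of the process, how long until reward becomes
#' available when the schedule is reset (a fresh interval sampled) every
#' `reset_every` seconds before availability. For the memoryless exponential
#' law this distribution is identical to the no-reset interval distribution —
#' a reset is equivalent to maintaining the original interval — which is why
#' premature presses carry essentially no temporal cost in that variant.
#' The property is exponential-specific, so gamma specs are rejected.
#'
#' @param spec An exponential [schedule_spec()].
#' @param n Number of independent waiting times to draw.
#' @param reset_every Period of premature resets, seconds; `Inf` means no
#'   resets (then the result is just [sample_interval()]).
#' @return Numeric vector of `n` waiting times (seconds).
#' @export
time_to_availability_after_reset <- function(spec, n = 1L, reset_every = Inf) {
  stopifnot(inherits(spec, "schedule_spec"))
  if (spec$variant != "exponential") {
    stop("reset-invariance is an exponential-schedule property; got gamma spec")
  }
  if (!is.numeric(reset_every) || reset_every <= 0) {
    stop("`reset_every` must be positive")
  }
  wait <- numeric(n)
  acc <- numeric(n)
  active <- seq_len(n)
  while (length(active)) {
    lam <- rexp(length(active), rate = spec$rate)
    done <- lam <= reset_every
    wait[active[done]] <- acc[active[done]] + lam[done]
    acc[active[!done]] <- acc[active[!done]] + reset_every
    active <- active[!done]
  }
  wait
}

#' Monte-Carlo check of a schedule's mean interval
#'
#' @param spec A [schedule_spec()].
#' @param n Number of draws (>= 1000).
#' @return List with `mean`, `se` (standard error of the mean), and `n`.
#' @export
mean_interval_check <- function(spec, n = 100000L) {
  if (n < 1000L) stop("`n` must be at least 1000 for a stable estimate")
  x <- sample_interval(spec, n)
  list(mean = mean(x), se = sd(x) / sqrt(n), n = n)
}
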