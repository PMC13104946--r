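#' Specify a synthetic forager agent
#'
#' Three heuristic policies are available; none observes the sampled interval
#' or the availability state directly — only (noisy) cue values and reward
#' outcomes, matching the information set of a real subject.
#'
#' * `"random"`: presses at exponential waiting times (`base_push_rate`) and
#'   picks a patch uniformly — by construction the behavior the rate-matched
#'   null model assumes.
#' * `"cue_threshold"`: polls the patches every `poll_dt` seconds, reads each
#'   patch's cue with zero-mean Gaussian noise of sd
#'   `cue_noise_sd / sqrt(kappa)` plus a per-session per-patch calibration
#'   bias of sd `cue_bias_sd / sqrt(kappa)` (fast noise averages out over a
#'   session; the slow bias is what lets an unreliable cue misorder patches
#'   at the block level), converts the noisy reading to a perceived
#'   probability that a press would be rewarded (the cue itself in the
#'   exponential variant; `pnorm((A_hat - 1)/sd)` in the gamma variant, where
#'   reward requires the progression cue to have completed). A patch is
#'   *ready* when its perceived reward probability exceeds `cue_threshold`.
#'   The agent presses its current patch as soon as that patch is ready.
#'   When another patch becomes ready first, it makes a one-shot stay-or-go
#'   decision: it estimates the remaining wait at the current patch from the
#'   (noisy) cue — \eqn{m \log[(1-X)/(1-\mathrm{thr})]} for the exponential
#'   cue, \eqn{(1-A) m} for the gamma progression cue, with `m` the patch's
#'   mean interval — and switches with probability
#'   `plogis((wait - travel_time) / wait_scale)`, paying `travel_time`;
#'   otherwise it commits to waiting. Because the exponential cue recovers
#'   within seconds after a press while the gamma cue promises a wait on the
#'   order of the full interval, this single rule yields persistent
#'   within-patch pressing under exponential schedules and ready-patch
#'   harvesting (low self-transitions, switches directed toward the fast
#'   patch) under gamma schedules.
#' * `"rate_matching"`: presses at exponential waiting times and chooses a
#'   patch by softmax over exponentially weighted running reward-rate
#'   estimates (weight `learning_rate`, temperature `softmax_temperature`).
#'
#' `repress_prob` adds, after any press, a probability of a rapid follow-up
#' press at the same patch (mean latency `repress_delay`), emulating the
#' short-interval exploitation mode that makes pooled inter-push-interval
#' distributions bimodal.
#'
#' @param kind Policy, one of `"cue_threshold"`, `"random"`, `"rate_matching"`.
#' @param base_push_rate Press rate of the Poisson policies, 1/seconds.
#' @param cue_threshold Perceived reward probability required to press, in
#'   `[0, 1]`.
#' @param cue_noise_sd Fast (per-poll) cue observation noise scale; the
#'   effective sd is `cue_noise_sd / sqrt(kappa)`, so the concentration
#'   parameter plays the same reliability role as in the rendered stimulus.
#' @param cue_bias_sd Scale of the slow per-session, per-patch cue
#'   calibration bias; effective sd `cue_bias_sd / sqrt(kappa)`.
#' @param learning_rate Per-press EMA weight of the reward-rate estimates.
#' @param softmax_temperature Softmax temperature over reward estimates.
#' @param travel_time Seconds to move between patches.
#' @param wait_scale Softness (seconds) of the stay-or-go comparison between
#'   the estimated remaining wait and the travel time.
#' @param repress_prob Probability of a rapid same-patch follow-up press.
#' @param repress_delay Mean latency of the follow-up press, seconds.
#' @param poll_dt Cue polling resolution of the threshold policy, seconds.
#' @return Object of class `"agent_spec"`.
#' @export
agent_spec <- function(kind = c("cue_threshold", "random", "rate_matching"),
                       base_push_rate = 0.2, cue_threshold = 0.3,
                       cue_noise_sd = 0.25, cue_bias_sd = 0.25,
                       learning_rate = 0.2,
                       softmax_temperature = 0.25, travel_time = 3,
                       wait_scale = 4, repress_prob = 0,
                       repress_delay = 0.4, poll_dt = 0.25) {
  kind <- match.arg(kind)
  stopifnot(base_push_rate > 0, cue_threshold >= 0, cue_threshold <= 1,
            cue_noise_sd >= 0, cue_bias_sd >= 0,
            learning_rate >= 0, learning_rate <= 1,
            softmax_temperature > 0, travel_time >= 0, wait_scale > 0,
            repress_prob >= 0, repress_prob <= 1, repress_delay > 0,
            poll_dt > 0)
  structure(list(kind = kind, base_push_rate = base_push_rate,
                 cue_threshold = cue_threshold, cue_noise_sd = cue_noise_sd,
                 cue_bias_sd = cue_bias_sd, learning_rate = learning_rate,
                 softmax_temperature = softmax_temperature,
                 travel_time = travel_time, wait_scale = wait_scale,
                 repress_prob = repress_prob, repress_delay = repress_delay,
                 poll_dt = poll_dt),
            class = "agent_spec")
}

#' Configure one session (block)
#'
#' Defaults encode the study conditions: three patches with mean
#' reward-availability intervals of 7, 14 and 21 s (fast/med/slow), blocks of
#' about 15 minutes, gamma shape 10.
#'
#' @param variant `"exponential"` or `"gamma"` (sets both the interval law
#'   and the cue semantics).
#' @param mean_intervals Named vector of per-patch mean intervals, seconds.
#' @param kappa Cue reliability (concentration) for the session.
#' @param duration Session length, seconds.
#' @param seed Integer seed; every source of randomness in the session flows
#'   from it.
#' @param block_id Label carried into event logs.
#' @param shape Gamma shape parameter.
#' @return Object of class `"session_config"`.
#' @export
session_config <- function(variant = c("exponential", "gamma"),
                           mean_intervals = c(fast = 7, med = 14, slow = 21),
                           kappa = 4, duration = 900, seed = 1L,
                           block_id = "b1", shape = 10) {
  variant <- match.arg(variant)
  if (!identical(sort(names(mean_intervals)), sort(PATCHES))) {
    stop("`mean_intervals` must be named fast, med, slow")
  }
  stopifnot(all(mean_intervals > 0), duration >= 0, kappa > 0)
  structure(list(variant = variant,
                 mean_intervals = mean_intervals[PATCHES], kappa = kappa,
                 duration = duration, seed = as.integer(seed),
                 block_id = as.character(block_id), shape = shape),
            class = "session_config")
}

.empty_log <- function(config) {
  log <- data.frame(t_s = numeric(0), patch = character(0),
                    rewarded = logical(0))
  attr(log, "config") <- config
  class(log) <- c("session_log", "data.frame")
  log
}

.as_session_log <- function(t, patch, rewarded, config) {
  log <- data.frame(t_s = t, patch = patch, rewarded = rewarded)
  attr(log, "config") <- config
  class(log) <- c("session_log", "data.frame")
  log
}

#' @export
print.session_log <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<session_log> %d pushes, %.0f s, %s variant, kappa = %.3g (block %s)\n",
              nrow(x), if (nrow(x)) max(x$t_s) else 0,
              cfg$variant, cfg$kappa, cfg$block_id))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

# perceived probability that a press right now would be rewarded, given a
# noisy cue reading; the gamma cue is a progression signal, so reward
# requires completion (A >= 1) and the readout is the posterior mass above 1
.perceived_reward_prob <- function(Xhat, sigma, variant) {
  if (variant == "exponential") {
    pmin(pmax(Xhat, 0), 1)
  } else if (sigma == 0) {
    as.numeric(Xhat >= 1)
  } else {
    pnorm((Xhat - 1) / sigma)
  }
}

# estimated remaining wait (s) until the current patch becomes worth pressing,
# read off the noisy cue; m is the patch's mean availability interval
.estimated_wait <- function(Xhat, m, thr, variant) {
  x <- pmin(pmax(Xhat, 0), 1)
  if (variant == "exponential") {
    if (thr >= 1) return(Inf)
    max(m * (log1p(-x) - log1p(-thr)), 0)
  } else {
    (1 - x) * m
  }
}

.run_random <- function(config, agent) {
  dur <- config$duration
  t <- numeric(0)
  last <- 0
  repeat {
    batch <- cumsum(rexp(max(16L, ceiling(agent$base_push_rate * dur)),
                         agent$base_push_rate)) + last
    t <- c(t, batch)
    last <- t[length(t)]
    if (last > dur) break
  }
  t <- t[t <= dur]
  if (!length(t)) return(.empty_log(config))
  patch <- sample(PATCHES, length(t), replace = TRUE)
  procs <- .init_procs(config)
  rewarded <- logical(length(t))
  for (i in seq_along(t)) {
    res <- press(procs[[patch[i]]], t[i])
    procs[[patch[i]]] <- res$process
    rewarded[i] <- res$outcome$rewarded
  }
  .as_session_log(t, patch, rewarded, config)
}

.init_procs <- function(config) {
  procs <- lapply(PATCHES, function(p) {
    patch_process(p, schedule_spec(config$variant,
                                   config$mean_intervals[[p]],
                                   shape = config$shape))
  })
  names(procs) <- PATCHES
  procs
}

.run_cue_threshold <- function(config, agent) {
  dur <- config$duration
  sigma <- agent$cue_noise_sd / sqrt(config$kappa)
  bias <- rnorm(3L, 0, agent$cue_bias_sd / sqrt(config$kappa))
  procs <- .init_procs(config)
  t_ev <- numeric(0); p_ev <- character(0); r_ev <- logical(0)
  do_press <- function(j, when) {
    res <- press(procs[[j]], when)
    procs[[j]] <<- res$process
    t_ev <<- c(t_ev, when); p_ev <<- c(p_ev, j)
    r_ev <<- c(r_ev, res$outcome$rewarded)
  }
  t <- 0
  cur <- NA_character_
  committed <- FALSE  # decided to wait out the current patch
  press_and_advance <- function(j, when) {
    do_press(j, when)
    cur <<- j
    committed <<- FALSE
    if (runif(1) < agent$repress_prob) {
      when2 <- when + rexp(1, 1 / agent$repress_delay)
      if (when2 <= dur) {
        do_press(j, when2)
        when <- when2
      }
    }
    when
  }
  while (t <= dur) {
    X <- vapply(procs, cue_value, numeric(1), now = t)
    Xhat <- X + bias + rnorm(3L, 0, sigma)
    perceived <- .perceived_reward_prob(Xhat, sigma, config$variant)
    ready <- perceived >= agent$cue_threshold
    cur_i <- match(cur, PATCHES)
    if (!is.na(cur_i) && ready[cur_i]) {
      # current patch worth pressing: harvest it
      t <- press_and_advance(cur, t) + agent$poll_dt
    } else if (any(ready)) {
      others <- which(ready)
      others <- others[others != ifelse(is.na(cur_i), 0L, cur_i)]
      if (!length(others)) {
        t <- t + agent$poll_dt
      } else if (committed) {
        t <- t + agent$poll_dt  # waiting out the current patch
      } else {
        j <- PATCHES[others[which.max(perceived[others])]]
        if (is.na(cur_i)) {
          # session start: no current patch, just go
          t <- press_and_advance(j, t) + agent$poll_dt
        } else {
          wait_cur <- .estimated_wait(Xhat[cur_i],
                                      config$mean_intervals[[cur]],
                                      agent$cue_threshold, config$variant)
          p_go <- stats::plogis((wait_cur - agent$travel_time) /
                                  agent$wait_scale)
          if (runif(1) < p_go) {
            when <- t + agent$travel_time
            if (when > dur) break
            t <- press_and_advance(j, when) + agent$poll_dt
          } else {
            committed <- TRUE
            t <- t + agent$poll_dt
          }
        }
      }
    } else {
      t <- t + agent$poll_dt
    }
  }
  if (!length(t_ev)) return(.empty_log(config))
  .as_session_log(t_ev, p_ev, r_ev, config)
}

.run_rate_matching <- function(config, agent) {
  dur <- config$duration
  procs <- .init_procs(config)
  v <- c(fast = 0.5, med = 0.5, slow = 0.5)  # optimistic-neutral init
  t_ev <- numeric(0); p_ev <- character(0); r_ev <- logical(0)
  t <- rexp(1, agent$base_push_rate)
  while (t <= dur) {
    pr <- exp(v / agent$softmax_temperature)
    j <- sample(PATCHES, 1L, prob = pr / sum(pr))
    res <- press(procs[[j]], t)
    procs[[j]] <- res$process
    t_ev <- c(t_ev, t); p_ev <- c(p_ev, j)
    r_ev <- c(r_ev, res$outcome$rewarded)
    v[j] <- (1 - agent$learning_rate) * v[j] +
      agent$learning_rate * as.numeric(res$outcome$rewarded)
    gap <- rexp(1, agent$base_push_rate)
    if (runif(1) < agent$repress_prob) {
      t2 <- t + rexp(1, 1 / agent$repress_delay)
      if (t2 <= dur && t2 < t + gap) {
        res <- press(procs[[j]], t2)
        procs[[j]] <- res$process
        t_ev <- c(t_ev, t2); p_ev <- c(p_ev, j)
        r_ev <- c(r_ev, res$outcome$rewarded)
        v[j] <- (1 - agent$learning_rate) * v[j] +
          agent$learning_rate * as.numeric(res$outcome$rewarded)
      }
    }
    t <- t + gap
  }
  if (!length(t_ev)) return(.empty_log(config))
  .as_session_log(t_ev, p_ev, r_ev, config)
}

#' Simulate one session of the foraging task
#'
#' Event-driven simulation of an agent interacting with the three patch
#' schedules. The session seed determines every random draw, so identical
#' configuration yields an identical log.
#'
#' @param config A [session_config()].
#' @param agent An [agent_spec()].
#' @return A `"session_log"`: data.frame with columns `t_s` (strictly
#'   increasing press times, seconds), `patch`, `rewarded`, and the
#'   configuration attached as attribute `"config"`.
#' @examples
#' log <- run_session(session_config("gamma", duration = 300, seed = 7),
#'                    agent_spec("cue_threshold"))
#' push_fraction(log)
#' @export
run_session <- function(config, agent) {
  stopifnot(inherits(config, "session_config"), inherits(agent, "agent_spec"))
  set.seed(config$seed)
  if (config$duration == 0) return(.empty_log(config))
  switch(agent$kind,
         random = .run_random(config, agent),
         cue_threshold = .run_cue_threshold(config, agent),
         rate_matching = .run_rate_matching(config, agent))
}

#' Simulate a set of blocks under one condition
#'
#' Convenience wrapper running [run_session()] for `n_blocks` seeds derived
#' from `base_seed`.
#'
#' @param n_blocks Number of blocks.
#' @param base_seed Integer; block `i` uses seed `(base_seed + i) mod 2^31-1`.
#' @param agent An [agent_spec()].
#' @param ... Passed to [session_config()] (variant, kappa, duration, ...).
#' @return List of `"session_log"` objects.
#' @export
run_blocks <- function(n_blocks, base_seed, agent, ...) {
  lapply(seq_len(n_blocks), function(i) {
    run_session(session_config(...,
                               seed = (base_seed + i) %% 2147483647,
                               block_id = sprintf("b%03d", i)),
                agent)
  })
}
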