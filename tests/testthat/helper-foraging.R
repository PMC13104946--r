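# build a session_log by hand (for worked examples)
mk_log <- function(t, patch, rewarded = rep(FALSE, length(t)),
                   variant = "exponential", kappa = 4, block = "b1") {
  log <- data.frame(t_s = t, patch = patch, rewarded = rewarded)
  attr(log, "config") <- session_config(variant = variant, kappa = kappa,
                                        duration = max(t, 1), seed = 1L,
                                        block_id = block)
  class(log) <- c("session_log", "data.frame")
  log
}

# absolute circular difference in [0, pi]
circ_err <- function(a, b) abs(Arg(exp(1i * (a - b))))

# a patch process with prescribed state (bypasses the sampled interval)
fixed_process <- function(patch = "fast", variant = "exponential",
                          mean_interval = 7, lambda = NULL, t_last = 0) {
  p <- patch_process(patch, schedule_spec(variant, mean_interval))
  p$t_last <- t_last
  if (!is.null(lambda)) p$lambda <- lambda
  p
}
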