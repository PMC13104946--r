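test_that("push fractions count events and ignore order", {
  log <- mk_log(1:4, c("fast", "fast", "med", "slow"))
  expect_equal(push_fraction(log),
               c(fast = 0.5, med = 0.25, slow = 0.25))
  expect_equal(push_fraction(mk_log(1:3, rep("fast", 3))),
               c(fast = 1, med = 0, slow = 0))
  perm <- mk_log(1:4, c("slow", "fast", "med", "fast"))
  expect_equal(push_fraction(perm), push_fraction(log))
  expect_error(push_fraction(mk_log(numeric(0), character(0))), "empty")
})

test_that("per-patch IPIs span intervening pushes elsewhere", {
  log <- mk_log(c(1, 1.5, 2, 3, 4), c("fast", "med", "fast", "slow", "fast"))
  ipi <- ipi_distribution(log, "fast")
  expect_equal(ipi$intervals, c(1, 2))
  expect_equal(ipi$median, 1.5)
  expect_identical(ipi_distribution(log, "med")$intervals, numeric(0))
  expect_true(is.na(ipi_distribution(log, "med")$median))
})

test_that("transition matrix matches hand counts", {
  log <- mk_log(1:5, c("fast", "fast", "med", "fast", "slow"))
  tm <- transition_matrix(log)
  expect_equal(unname(tm$P["fast", ]), c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(unname(tm$P["med", ]), c(1, 0, 0))
  # transitions out of med/slow: med->fast only => P(->F | not F) = 1
  expect_identical(tm$p_fast_given_notfast, 1)
  alt <- mk_log(1:6, rep(c("fast", "med"), 3))
  tma <- transition_matrix(alt)
  expect_identical(tma$P["fast", "med"], 1)
  expect_identical(tma$P["med", "fast"], 1)
})

test_that("transition probabilities of random labels are uniform", {
  set.seed(31)
  n <- 1e5
  log <- mk_log(seq_len(n), sample(c("fast", "med", "slow"), n, TRUE))
  tm <- transition_matrix(log)
  se <- sqrt(1 / 3 * 2 / 3 / (n / 3))
  expect_true(all(abs(tm$P - 1 / 3) < 3 * se))
  expect_lt(abs(tm$p_fast_given_notfast - 1 / 3), 3 * se)
})

test_that("visit segmentation finds maximal same-patch runs", {
  log <- mk_log(c(1, 3, 5, 6, 9), c("fast", "fast", "med", "med", "fast"))
  v <- segment_visits(log)
  expect_identical(v$patch, c("fast", "med", "fast"))
  expect_equal(v$t_first, c(1, 5, 9))
  expect_equal(v$t_last, c(3, 6, 9))
  expect_identical(v$n_pushes, c(2L, 2L, 1L))
  # single push: one zero-length visit
  v1 <- segment_visits(mk_log(2, "slow"))
  expect_identical(nrow(v1), 1L)
  expect_equal(stay_times(v1)$stay, 0)
  # locality: concatenating logs concatenates visits
  a <- mk_log(1:3, c("fast", "fast", "med"))
  b <- mk_log(4:5, c("slow", "slow"))
  ab <- mk_log(1:5, c("fast", "fast", "med", "slow", "slow"))
  expect_equal(segment_visits(ab),
               rbind(segment_visits(a), segment_visits(b)),
               ignore_attr = TRUE)
})

test_that("stay and return times follow the visit formulas", {
  log <- mk_log(c(10, 12, 15, 20, 40, 41),
                c("fast", "fast", "fast", "med", "fast", "fast"))
  v <- segment_visits(log)
  st <- stay_times(v)
  expect_equal(st$stay[st$patch == "fast"], c(5, 1))
  # left fast at 15, returned at 40
  rt <- return_times(v)
  expect_equal(rt$return_time[rt$patch == "fast"], 25)
  expect_identical(nrow(return_times(segment_visits(mk_log(1, "med")))), 0L)
  # properties on a random log
  set.seed(32)
  rl <- mk_log(cumsum(runif(200, 0.1, 3)),
               sample(c("fast", "med", "slow"), 200, TRUE))
  vv <- segment_visits(rl)
  expect_true(all(stay_times(vv)$stay >= 0))
  expect_true(all(return_times(vv)$return_time > 0))
})

test_that("null model is rate-matched and label-uniform in expectation", {
  set.seed(33)
  log <- mk_log(cumsum(rexp(300, 0.25)),
                sample(c("fast", "med", "slow"), 300, TRUE))
  nm <- null_model(log, n_reps = 300)
  expect_equal(nm$rate, 299 / (log$t_s[300] - log$t_s[1]))
  # visits under uniform labels have mean length 1.5 pushes; stay means of
  # the three patches should agree with each other closely
  expect_lt(max(nm$stay) - min(nm$stay), 0.15 * mean(nm$stay))
  expect_lt(max(nm$return_time) - min(nm$return_time),
            0.15 * mean(nm$return_time))
  expect_error(null_model(log, n_reps = 0), "at least 1")
})

test_that("normalization is a ratio and invariant to time rescaling", {
  expect_identical(normalize_metric(10, 5), 2)
  expect_identical(normalize_metric(7.3, 7.3), 1)
  expect_warning(out <- normalize_metric(3, 0), "not positive")
  expect_true(is.na(out))
  set.seed(34)
  log <- mk_log(cumsum(rexp(200, 0.2)),
                sample(c("fast", "med", "slow"), 200, TRUE))
  scaled <- mk_log(log$t_s * 3.5, log$patch)
  real <- vapply(split(stay_times(segment_visits(log))$stay,
                       stay_times(segment_visits(log))$patch), mean,
                 numeric(1))
  real_s <- vapply(split(stay_times(segment_visits(scaled))$stay,
                         stay_times(segment_visits(scaled))$patch), mean,
                   numeric(1))
  set.seed(77)
  n1 <- null_model(log, 100)
  set.seed(77)
  n2 <- null_model(scaled, 100)
  # same RNG stream: surrogate draws scale exactly with the rate, so the
  # normalized ratios agree exactly
  expect_equal(real / n1$stay[names(real)],
               real_s / n2$stay[names(real_s)], tolerance = 1e-12)
})

test_that("pooled Spearman tracks quality ordering and its absence", {
  set.seed(35)
  ordered <- t(replicate(20, sort(c(0.2, 0.3, 0.5) + rnorm(3, 0, 0.02),
                                  decreasing = TRUE)))
  colnames(ordered) <- c("fast", "med", "slow")
  qs <- quality_rank_spearman(ordered)
  expect_gt(qs$rho, 0.9)
  expect_lt(qs$p, 1e-6)
  expect_identical(qs$n, 60L)
  # permutation oracle: fractions independent of rank
  rnd <- t(replicate(1e4, { x <- runif(3); x / sum(x) }))
  colnames(rnd) <- c("fast", "med", "slow")
  expect_lt(abs(quality_rank_spearman(rnd)$rho), 0.03)
  # constant fractions: undefined, flagged
  flat <- matrix(1 / 3, 4, 3, dimnames = list(NULL, c("fast", "med", "slow")))
  expect_true(quality_rank_spearman(flat)$flagged)
  expect_error(quality_rank_spearman(ordered[1, , drop = FALSE]), "2 blocks")
})

test_that("per-block exact Spearman has the 3-point permutation null", {
  fr <- matrix(c(0.6, 0.3, 0.1), 1, dimnames = list(NULL,
                                                    c("fast", "med", "slow")))
  pb <- per_block_spearman(fr)
  expect_identical(pb$rho, 1)
  expect_equal(pb$p, 1 / 3)  # 2 of 6 permutations reach |rho| = 1
})

test_that("continuous push rate is the stated piecewise inverse-IPI series", {
  log <- mk_log(c(0, 2, 2.5), c("fast", "fast", "med"))
  cpr <- continuous_push_rate(log, window = 2, dt = 0.25)
  expect_equal(cpr$step$rate, c(0.5, 2))
  expect_equal(cpr$step$t_start, c(0, 2))
  # periodic pushes: normalized rate identically 1
  per <- mk_log(seq(0, 100, by = 4), rep("fast", 26))
  cp <- continuous_push_rate(per)
  expect_true(all(abs(cp$series$rate_norm - 1) < 1e-12))
  expect_true(all(abs(cp$series$rate_smooth - 1) < 1e-12))
  # smoothing approximately preserves the series mean
  set.seed(36)
  rl <- mk_log(cumsum(rexp(400, 0.5)), rep("fast", 400))
  cr <- continuous_push_rate(rl)
  expect_lt(abs(mean(cr$series$rate_smooth) - mean(cr$series$rate_norm)),
            0.05 * mean(cr$series$rate_norm))
  dup <- mk_log(c(0, 1, 1, 2), rep("fast", 4))
  expect_warning(continuous_push_rate(dup), "duplicate")
})

test_that("windowed push fractions sum to 1 and detect flat allocation", {
  one <- mk_log(seq(5, 295, by = 5), rep("med", 59))
  wf <- windowed_push_fraction(list(one), window = 60, step = 20)
  med_rows <- wf$summary[wf$summary$patch == "med", ]
  expect_true(all(med_rows$mean[!is.na(med_rows$mean)] == 1))
  sums <- apply(wf$frac, c(1, 2), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
  # stationary random agent: flat courses near 1/3
  logs <- run_blocks(15, 9000, agent_spec("random"),
                     variant = "exponential", kappa = 4, duration = 600)
  wf2 <- windowed_push_fraction(logs)
  avg <- tapply(wf2$summary$mean, wf2$summary$patch, mean, na.rm = TRUE)
  expect_true(all(abs(avg - 1 / 3) < 0.04))
})

test_that("time-resolved Spearman separates ordered from random allocation", {
  # every window holds pushes ordered fast > med > slow
  logs <- lapply(1:4, function(s) {
    set.seed(s)
    t_f <- seq(0.5, 600, by = 3)
    t_m <- seq(1, 600, by = 6)
    t_s <- seq(1.5, 600, by = 12)
    tt <- c(t_f, t_m, t_s)
    ord <- order(tt)
    mk_log(tt[ord], c(rep("fast", length(t_f)), rep("med", length(t_m)),
                      rep("slow", length(t_s)))[ord])
  })
  tc <- timeresolved_spearman(logs, window = 60, step = 30)
  expect_true(all(abs(tc$mean_rho - 1) < 1e-12))
  rnd <- run_blocks(15, 9500, agent_spec("random"),
                    variant = "exponential", kappa = 4, duration = 600)
  tcr <- timeresolved_spearman(rnd)
  expect_lt(abs(mean(tcr$mean_rho, na.rm = TRUE)), 0.1)
})

test_that("block metrics are deterministic given log and seed", {
  log <- run_session(session_config("gamma", duration = 400, seed = 44),
                     agent_spec("cue_threshold"))
  set.seed(1234); a <- block_metrics(log, null_reps = 50)
  set.seed(1234); b <- block_metrics(log, null_reps = 50)
  expect_identical(a, b)
  expect_equal(sum(a$push_fraction), 1)
  expect_true(all(abs(rowSums(a$transitions$P) - 1) < 1e-12))
})
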