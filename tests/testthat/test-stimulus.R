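test_that("amplitude spectrum follows the 1/f law", {
  S <- make_amplitude_spectrum(8)
  expect_identical(S[1, 1], 0)
  # frequency (3, 4): 0-based indices 3, 4 -> 1-based [4, 5]
  expect_equal(S[4, 5], 0.2)
  # radial symmetry S_A(u, v) = S_A(-u, -v)
  idx <- function(k, N) ((-k) %% N) + 1L
  for (u in 0:7) for (v in 0:7) {
    expect_identical(S[u + 1, v + 1], S[idx(u, 8), idx(v, 8)])
  }
  expect_error(make_amplitude_spectrum(7), "even")
  expect_error(make_amplitude_spectrum(4), "even integer >= 8")
})

test_that("spectrum updates keep Hermitian symmetry and real frames", {
  set.seed(21)
  f <- spectrum_field(16, alpha = 0.3)
  for (i in 1:3) f <- step_spectrum(f)
  N <- f$N
  conj_gap <- max(abs(f$S[foragesim:::.conj_index(N)] - Conj(f$S)))
  expect_identical(conj_gap, 0)
  fr <- render_frame(f, 0, 0)
  expect_lt(max(abs(Im(fr$field))), 1e-9 * max(abs(Re(fr$field))))
})

test_that("coefficients are stationary AR(1) with variance S_A^2", {
  set.seed(22)
  f <- spectrum_field(8, alpha = 1)
  n <- 4000
  tr <- matrix(0i, n, 2)
  for (i in seq_len(n)) {
    f <- step_spectrum(f)
    tr[i, ] <- c(f$S[2, 1], f$S[3, 3])
  }
  for (j in 1:2) {
    ij <- list(c(2, 1), c(3, 3))[[j]]
    sa2 <- f$S_A[ij[1], ij[2]]^2
    om <- f$omega[ij[1], ij[2]]
    # variance of Re and Im both equal S_A^2 (4 SE of a variance estimate)
    for (part in list(Re(tr[, j]), Im(tr[, j]))) {
      se <- sd((part - mean(part))^2) / sqrt(n)
      expect_lt(abs(var(part) - sa2), 4 * se)
    }
    # lag-k autocorrelation tracks omega^k
    rho <- acf(Re(tr[, j]), lag.max = 3, plot = FALSE)$acf[2:4]
    expect_lt(max(abs(rho - om^(1:3))), 0.06)
  }
})

test_that("cue-to-phase map is the stated affine map", {
  expect_identical(phase_from_cue(0), -2 * pi / 3)
  expect_identical(phase_from_cue(1), 2 * pi / 3)
  expect_equal(phase_from_cue(0.5, 0, pi), pi / 2)
  expect_error(phase_from_cue(1.2), "\\[0, 1\\]")
})

test_that("rendered frames encode the cue phase in proportion to kappa", {
  set.seed(23)
  f <- spectrum_field(32, alpha = 0.1)
  # overwhelming cue: every pixel's phase equals theta
  fr <- render_frame(f, 1e8, 1.0)
  expect_lt(max(circ_err(fr$phase, 1.0)), 1e-6)
  d <- decode_phase(fr)
  expect_equal(d$theta_hat, 1.0, tolerance = 1e-6)
  expect_equal(d$R, 1, tolerance = 1e-6)
  # kappa = 0: no phase coherence, tiny resultant, theta uninformative
  R0 <- replicate(40, decode_phase(render_frame(
    spectrum_field(32, alpha = 0.1), 0, 1.0))$R)
  expect_lt(mean(R0), 0.1)
  expect_error(decode_phase(numeric(0)), "empty")
})

test_that("decoder circular error decreases with cue concentration", {
  set.seed(24)
  kappas <- c(0.5, 1, 2, 4, 8)
  errs <- rowMeans(replicate(60, {
    f <- spectrum_field(32, alpha = 0.1)
    th <- runif(1, -pi, pi)
    vapply(kappas, function(k) {
      circ_err(decode_phase(render_frame(f, k, th))$theta_hat, th)
    }, numeric(1))
  }))
  expect_true(all(diff(errs) < 0))
})

test_that("color lookup is periodic, binned half-open, and phase-pure", {
  lut <- make_phase_lut(256)
  expect_identical(nrow(lut), 256L)
  expect_true(all(lut$R >= 0 & lut$R <= 255))
  # constant-phase field -> uniform color
  col <- phase_to_color(matrix(0.7, 4, 4), lut)
  expect_identical(length(unique(as.vector(col[, , 1]))), 1L)
  # periodicity
  phi <- seq(-3, 3, by = 0.37)
  expect_identical(phase_to_color(phi, lut), phase_to_color(phi + 2 * pi, lut))
  # a phase exactly on a bin edge falls in the lower bin
  edge <- lut$phase_bin_low[10]
  expect_identical(as.vector(phase_to_color(edge, lut)),
                   c(lut$R[9], lut$G[9], lut$B[9]))
  expect_identical(as.vector(phase_to_color(edge + 1e-9, lut)),
                   c(lut$R[10], lut$G[10], lut$B[10]))
  expect_error(phase_to_color(0.5, lut[0, ]), "nonempty")
})

test_that("texture frames have ~1/f spectra; white noise is flat", {
  set.seed(25)
  f <- spectrum_field(64, alpha = 0.1)
  frames <- lapply(1:8, function(i) {
    f <<- step_spectrum(f)
    render_frame(f, 0, 0)
  })
  expect_lt(abs(spectral_slope(frames)$slope + 1), 0.15)
  wn <- lapply(1:4, function(i) matrix(rnorm(64^2), 64))
  expect_lt(abs(spectral_slope(wn)$slope), 0.1)
  # doubling the grid leaves the slope unchanged within tolerance
  set.seed(26)
  f2 <- spectrum_field(128, alpha = 0.1)
  frames2 <- lapply(1:4, function(i) {
    f2 <<- step_spectrum(f2)
    render_frame(f2, 0, 0)
  })
  expect_lt(abs(spectral_slope(frames2)$slope -
                  spectral_slope(frames)$slope), 0.15)
  expect_error(spectral_slope(frames[[1]], max_radius = 2), "radial bins")
})

test_that("a rendered cue trajectory is recovered more faithfully at high kappa", {
  set.seed(27)
  p <- fixed_process("fast", "exponential", 7)
  ts <- seq(0.5, 18, by = 1.5)
  X <- vapply(ts, function(tt) cue_value(p, tt), numeric(1))
  theta <- phase_from_cue(X)
  mae <- vapply(c(0.5, 8), function(k) {
    f <- spectrum_field(32, alpha = 0.1)
    xhat <- vapply(theta, function(th) {
      f <<- step_spectrum(f)
      th_hat <- decode_phase(render_frame(f, k, th))$theta_hat
      min(max((th_hat + 2 * pi / 3) / (4 * pi / 3), 0), 1)
    }, numeric(1))
    mean(abs(xhat - X))
  }, numeric(1))
  expect_lt(mae[2], mae[1])
  expect_lt(mae[2], 0.1)
})
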