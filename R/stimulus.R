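#' Scale-invariant spatial amplitude spectrum
#'
#' Builds the 1/f amplitude law on an `N x N` grid of integer DFT
#' frequencies: \eqn{S_A(u, v) = (u^2 + v^2)^{-1/2}} for \eqn{(u,v) \neq (0,0)}
#' and 0 at DC. Frequencies use the standard DFT layout with DC at index
#' `[1, 1]` and negative frequencies in the upper half.
#'
#' @param N Grid size in pixels; even, >= 8.
#' @return `N x N` numeric matrix of nonnegative amplitudes.
#' @export
make_amplitude_spectrum <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 8 || N %% 2 != 0) {
    stop("`N` must be a single even integer >= 8")
  }
  k <- c(0:(N / 2 - 1), seq(-N / 2, -1))
  r2 <- outer(k^2, k^2, `+`)
  S <- 1 / sqrt(r2)
  S[1, 1] <- 0
  S
}

# index of the conjugate partner (-u, -v) for every linear index of an N x N
# DFT grid (1-based)
.conj_index <- function(N) {
  i <- rep(0:(N - 1), times = N)
  j <- rep(0:(N - 1), each = N)
  ci <- (-i) %% N
  cj <- (-j) %% N
  cj * N + ci + 1L
}

# Hermitian symmetrization: for every conjugate pair keep the coefficient at
# the lower linear index as master and overwrite its partner with the complex
# conjugate; self-conjugate entries (DC, Nyquist lines) are forced real. This
# preserves the marginal variance S_A^2 of the retained half-plane.
.symmetrize <- function(S, conj_idx) {
  lin <- seq_along(S)
  m <- lin < conj_idx
  S[conj_idx[m]] <- Conj(S[lin[m]])
  sc <- lin == conj_idx
  S[sc] <- complex(real = Re(S[sc]))
  S
}

# complex innovation S_B = (R1 + i R2) * S_A with R1, R2 standard normal
.innovation <- function(S_A) {
  N <- nrow(S_A)
  (matrix(rnorm(N * N), N) + 1i * matrix(rnorm(N * N), N)) * S_A
}

#' Initialize the dynamic texture spectrum
#'
#' The texture is an independent AR(1) process per spatial frequency:
#' \deqn{S_f(u,v,t) = \omega(u,v) S_f(u,v,t-1) + \sqrt{1 - \omega(u,v)^2}\, S_B(u,v,t),}
#' with innovation \eqn{S_B = (R_1 + i R_2) S_A} and per-frequency persistence
#' \eqn{\omega(u,v) = e^{-\alpha S_A(u,v)}}. The \eqn{\sqrt{1-\omega^2}}
#' innovation scaling makes the process stationary from the first frame, with
#' marginal variance \eqn{S_A^2} in both the real and imaginary parts.
#' Hermitian symmetry is enforced after every update so the spatial pattern is
#' real-valued.
#'
#' As printed, `omega_form = "amplitude"` makes low spatial frequencies (large
#' `S_A`) decorrelate fastest; `"inverse"` (\eqn{\omega = e^{-\alpha/S_A}})
#' reverses that direction and is provided as a configuration switch.
#'
#' @param N Grid size (even, >= 8).
#' @param alpha Temporal decay constant (dimensionless, > 0).
#' @param omega_form `"amplitude"` for \eqn{e^{-\alpha S_A}} or `"inverse"`
#'   for \eqn{e^{-\alpha / S_A}}.
#' @return Object of class `"spectrum_field"`: list with the coefficient grid
#'   `S` (complex), amplitude law `S_A`, persistence grid `omega`, frame
#'   counter `t`, and bookkeeping indices.
#' @seealso [step_spectrum()], [render_frame()]
#' @export
spectrum_field <- function(N = 128, alpha = 0.1,
                           omega_form = c("amplitude", "inverse")) {
  omega_form <- match.arg(omega_form)
  S_A <- make_amplitude_spectrum(N)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive number")
  }
  omega <- if (omega_form == "amplitude") {
    exp(-alpha * S_A)
  } else {
    w <- exp(-alpha / pmax(S_A, .Machine$double.eps))
    w[S_A == 0] <- 1  # DC carries no texture power; value immaterial
    w
  }
  conj_idx <- .conj_index(N)
  S <- .symmetrize(.innovation(S_A), conj_idx)
  structure(list(N = N, alpha = alpha, omega_form = omega_form, S_A = S_A,
                 omega = omega, S = S, t = 0L, conj_idx = conj_idx),
            class = "spectrum_field")
}

#' Advance the texture spectrum by one frame
#'
#' @param field A [spectrum_field()].
#' @return The field at `t + 1` (AR(1) update plus Hermitian symmetrization).
#' @export
step_spectrum <- function(field) {
  stopifnot(inherits(field, "spectrum_field"))
  B <- .innovation(field$S_A)
  if (!identical(dim(B), dim(field$S))) stop("grid shape mismatch")
  field$S <- .symmetrize(field$omega * field$S +
                           sqrt(1 - field$omega^2) * B, field$conj_idx)
  field$t <- field$t + 1L
  field
}

#' @export
print.spectrum_field <- function(x, ...) {
  cat(sprintf("<spectrum_field> %d x %d, alpha = %.3g (%s), frame %d\n",
              x$N, x$N, x$alpha, x$omega_form, x$t))
  invisible(x)
}

#' Map a cue value to a stimulus phase angle
#'
#' Affine map \eqn{\theta = \theta_{min} + (\theta_{max} - \theta_{min}) X}
#' from the cue signal `X` in `[0, 1]` to the phase of the injected cue term.
#' The default endpoints traverse the blue-to-red arc of the Luv hue circle.
#'
#' @param X Cue value(s) in `[0, 1]`.
#' @param theta_min,theta_max Phase endpoints, radians.
#' @return Phase angle(s) in radians.
#' @export
phase_from_cue <- function(X, theta_min = -2 * pi / 3, theta_max = 2 * pi / 3) {
  if (any(X < 0 | X > 1)) stop("cue value `X` must lie in [0, 1]")
  theta_min + (theta_max - theta_min) * X
}

#' Render one stimulus frame
#'
#' Injects the cue term \eqn{\kappa e^{i\theta}} at the DC coefficient of the
#' texture spectrum (so the spatial mean color carries the cue) and applies
#' the inverse Fourier transform:
#' \deqn{C(x, y, t) = \mathrm{IFFT}[S_f(u, v, t) + \kappa e^{i\theta(t)}].}
#' The per-pixel phase `Arg C` is what the color lookup table renders; larger
#' `kappa` concentrates pixel phases around `theta`, i.e. raises cue
#' reliability relative to the texture variance.
#'
#' @param field A [spectrum_field()].
#' @param kappa Cue concentration (>= 0); 0 gives pure texture.
#' @param theta Cue phase angle, radians (see [phase_from_cue()]).
#' @return Object of class `"stim_frame"`: list with the complex `field`
#'   matrix, the `phase` matrix (radians), and `kappa`, `theta`.
#' @export
render_frame <- function(field, kappa, theta) {
  stopifnot(inherits(field, "spectrum_field"))
  if (kappa < 0) stop("`kappa` must be nonnegative")
  S <- field$S
  S[1, 1] <- S[1, 1] + kappa * exp(1i * theta)
  C <- fft(S, inverse = TRUE) / length(S)
  structure(list(field = C, phase = Arg(C), kappa = kappa, theta = theta),
            class = "stim_frame")
}

#' Decode the cue phase from a frame
#'
#' Circular mean of the per-pixel phases, with the mean resultant length `R`
#' as a coherence measure. Used to quantify how reliably a frame transmits
#' the encoded phase: decoding error shrinks as `kappa` grows.
#'
#' @param frame A `"stim_frame"` or a numeric/complex matrix of phases.
#' @return List with `theta_hat` (radians) and `R` in `[0, 1]`.
#' @export
decode_phase <- function(frame) {
  phase <- if (inherits(frame, "stim_frame")) {
    if (all(Mod(frame$field) == 0)) stop("all-zero field: phase undefined")
    frame$phase
  } else {
    if (length(frame) == 0) stop("empty frame")
    frame
  }
  z <- mean(exp(1i * phase))
  list(theta_hat = Arg(z), R = Mod(z))
}

#' Build the phase-to-color lookup table
#'
#' 256 (by default) half-open phase bins over `[-pi, pi)`, each assigned a
#' hue equally spaced on a circle of fixed lightness and chroma in CIE Luv
#' space, converted to 8-bit sRGB. Perceptual uniformity of Luv keeps equal
#' phase steps approximately equally discriminable.
#'
#' @param n_bins Number of phase bins.
#' @param L Luv lightness (0-100).
#' @param chroma Luv chroma radius.
#' @return `data.frame` of class `"phase_lut"` with columns
#'   `phase_bin_low`, `R`, `G`, `B` (0-255).
#' @export
make_phase_lut <- function(n_bins = 256L, L = 70, chroma = 60) {
  if (n_bins < 1L) stop("`n_bins` must be at least 1")
  lo <- seq(-pi, pi, length.out = n_bins + 1L)[seq_len(n_bins)]
  luv <- cbind(L, chroma * cos(lo), chroma * sin(lo))
  rgb <- convertColor(luv, from = "Luv", to = "sRGB", clip = TRUE)
  out <- data.frame(phase_bin_low = lo,
                    R = as.integer(round(255 * rgb[, 1])),
                    G = as.integer(round(255 * rgb[, 2])),
                    B = as.integer(round(255 * rgb[, 3])))
  class(out) <- c("phase_lut", "data.frame")
  out
}

#' Write a phase lookup table to CSV
#'
#' @param lut A [make_phase_lut()] table.
#' @param path Output CSV path.
#' @export
write_phase_lut <- function(lut, path) {
  stopifnot(inherits(lut, "phase_lut"))
  write.table(lut, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map per-pixel phases to 8-bit colors
#'
#' Phases are wrapped to `[-pi, pi)` and binned into the half-open bins of
#' the lookup table; a phase exactly on a bin edge falls in the lower bin.
#' The mapping is periodic: `phi` and `phi + 2*pi` map identically.
#'
#' @param phase Numeric matrix (or vector) of phases, radians.
#' @param lut A [make_phase_lut()] table.
#' @return Array `c(dim(phase), 3)` of 8-bit RGB values.
#' @export
phase_to_color <- function(phase, lut) {
  if (!inherits(lut, "phase_lut") || nrow(lut) < 1L) {
    stop("`lut` must be a nonempty phase_lut")
  }
  n <- nrow(lut)
  p <- ((phase + pi) %% (2 * pi)) - pi
  # epsilon guard keeps exact bin edges in the lower (half-open) bin despite
  # floating-point wrap error
  idx <- ceiling((p + pi) / (2 * pi) * n - 1e-9)
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  d <- if (is.null(dim(phase))) length(phase) else dim(phase)
  array(c(lut$R[idx], lut$G[idx], lut$B[idx]), dim = c(d, 3L))
}

#' Write a frame as an 8-bit PNG
#'
#' Requires the `png` package.
#'
#' @param frame A `"stim_frame"`.
#' @param lut A [make_phase_lut()] table.
#' @param path Output PNG path.
#' @export
write_frame_png <- function(frame, lut, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG frames requires the `png` package")
  }
  rgb <- phase_to_color(frame$phase, lut) / 255
  png::writePNG(rgb, path)
  invisible(path)
}

#' Radially averaged spectral slope of rendered frames
#'
#' Fits the slope of log radial-mean Fourier amplitude against log spatial
#' frequency, pooled over frames. For texture-only frames (`kappa = 0`) built
#' from the 1/f amplitude law the slope is approximately -1; white noise
#' gives approximately 0.
#'
#' @param frames A `"stim_frame"`, a numeric matrix, or a list of either.
#' @param max_radius Highest integer frequency bin to fit; defaults to
#'   `N/2 - 1` (rings fully contained in the grid).
#' @return List with `slope`, `intercept`, and the `radius`/`amplitude`
#'   profile used for the fit.
#' @export
spectral_slope <- function(frames, max_radius = NULL) {
  if (inherits(frames, "stim_frame") || is.matrix(frames)) frames <- list(frames)
  if (length(frames) < 1L) stop("need at least one frame")
  img <- function(f) if (inherits(f, "stim_frame")) Re(f$field) else f
  N <- nrow(img(frames[[1]]))
  k <- c(0:(N / 2 - 1), seq(-N / 2, -1))
  r <- round(sqrt(outer(k^2, k^2, `+`)))
  if (is.null(max_radius)) max_radius <- N / 2 - 1
  keep <- r >= 1 & r <= max_radius
  bins <- sort(unique(r[keep]))
  if (length(bins) < 3L) stop("fewer than 3 radial bins: grid too small")
  amp <- rowMeans(vapply(frames, function(f) {
    A <- Mod(fft(img(f)))
    as.numeric(tapply(A[keep], r[keep], mean))
  }, numeric(length(bins))))
  fit <- stats::lm.fit(cbind(1, log(bins)), log(amp))
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       radius = bins, amplitude = amp)
}
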