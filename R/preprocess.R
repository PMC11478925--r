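#' Frequency-domain spectrum
#'
#' Internal arrays are frequency-ascending (so also ppm-ascending for
#' protons); display functions reverse the axis per MRS convention.
#'
#' @param values Complex spectrum values.
#' @param ppm Strictly monotonic ppm axis, same length as `values`.
#' @param params Source acquisition parameters.
#' @param normalization `"raw"` or `"water_normalized"`.
#' @return An `mrs_spectrum` object.
#' @export
mrs_spectrum <- function(values, ppm, params,
                         normalization = c("raw", "water_normalized")) {
  normalization <- match.arg(normalization)
  stopifnot(length(values) == length(ppm), all(diff(ppm) > 0))
  structure(
    list(values = as.complex(values), ppm = as.numeric(ppm), params = params,
         normalization = normalization),
    class = "mrs_spectrum"
  )
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mrs_spectrum> %d points, %.2f to %.2f ppm, %s\n",
    length(x$values), min(x$ppm), max(x$ppm), x$normalization
  ))
  invisible(x)
}

#' Tidy a spectrum into a tibble
#'
#' @param x An `mrs_spectrum`.
#' @param ... Unused.
#' @return Tibble with columns `ppm`, `real`, `imag`, `magnitude`.
#' @export
tidy.mrs_spectrum <- function(x, ...) {
  tibble(
    ppm = x$ppm, real = Re(x$values), imag = Im(x$values),
    magnitude = Mod(x$values)
  )
}

fftshift_vec <- function(x) {
  n <- length(x)
  h <- n %/% 2
  c(x[(h + 1):n], x[1:h])
}

#' Eddy-current correction by water-reference phase subtraction
#'
#' Klose-style correction: each sample of the water-suppressed FID is
#' multiplied by `exp(-i arg(water_ref_k))`, removing the time-dependent
#' phase distortion that the water reference shares with the metabolite
#' signal. Sample magnitudes are unchanged. Where the water reference
#' magnitude falls below `threshold` times its maximum, the phase of the
#' previous usable sample is carried forward.
#'
#' @param fid Water-suppressed `mrs_fid`.
#' @param water_ref Water-reference `mrs_fid` with identical length and dwell.
#' @param threshold Relative magnitude below which the reference phase is
#'   considered unreliable.
#' @return Corrected `mrs_fid`.
#' @export
eddy_current_correct <- function(fid, water_ref, threshold = 1e-3) {
  if (length(fid$values) != length(water_ref$values)) {
    abort("fid and water_ref lengths differ")
  }
  if (abs(fid$dwell_s - water_ref$dwell_s) > 1e-12 * fid$dwell_s) {
    abort("fid and water_ref dwell times differ")
  }
  mag <- Mod(water_ref$values)
  ok <- mag > threshold * max(mag)
  ph <- Arg(water_ref$values)
  if (!ok[1]) ph[1] <- 0
  if (any(!ok)) {
    for (k in which(!ok)) if (k > 1) ph[k] <- ph[k - 1]
  }
  out <- fid$values * exp(-1i * ph)
  mrs_fid(out, fid$params, fid$kind)
}

#' Fourier transform an FID to a spectrum with a calibrated ppm axis
#'
#' The spectrum is scaled by the dwell time so that peak areas in Hz units
#' approximate the time-domain amplitudes, and the frequency axis is centred
#' on the transmitter frequency with water at 4.7 ppm. Optional Hanning
#' apodization (the scanner display mode) and zero filling are available;
#' the default fitting pipeline applies neither.
#'
#' @param fid An `mrs_fid`.
#' @param zero_fill_factor 1, 2 or 4.
#' @param apodization `"none"` or `"hanning"`.
#' @param hanning_width_ms Width of the Hanning half-window in ms (700 ms in
#'   the scanner display mode).
#' @return An `mrs_spectrum` on an ascending ppm axis.
#' @export
to_spectrum <- function(fid, zero_fill_factor = 1,
                        apodization = c("none", "hanning"),
                        hanning_width_ms = 700) {
  apodization <- match.arg(apodization)
  stopifnot(zero_fill_factor %in% c(1, 2, 4))
  p <- fid$params
  x <- fid$values
  if (apodization == "hanning") {
    t <- acq_time_axis(p)
    w_s <- hanning_width_ms / 1000
    w <- ifelse(t < w_s, 0.5 * (1 + cos(pi * t / w_s)), 0)
    x <- x * w
  }
  m <- length(x) * zero_fill_factor
  x <- c(x, complex(real = numeric(m - length(x))))
  sp <- fftshift_vec(fft(x)) * p$dwell_s
  df <- p$bandwidth_hz / m
  freq <- (seq_len(m) - 1 - m / 2) * df
  ppm <- WATER_PPM + freq / p$transmitter_mhz
  mrs_spectrum(sp, ppm, p, "raw")
}

# indices of the ppm window [lo, hi]
ppm_window <- function(spec, lo, hi) which(spec$ppm >= lo & spec$ppm <= hi)

apply_phase <- function(values, ppm, phi0_deg, phi1_deg_per_ppm,
                        pivot_ppm = 3.0) {
  values * exp(-1i * (phi0_deg + phi1_deg_per_ppm * (ppm - pivot_ppm)) * pi / 180)
}

#' Automatic zero- and first-order phasing
#'
#' Finds the zero-order phase (degrees) and first-order phase (degrees per
#' ppm, pivot 3.0 ppm) that put the spectrum into pure absorption over
#' 0.5-4.2 ppm. Phasing proceeds in two stages. First, the phases of the
#' strongest resolved peaks are measured by integrating the complex
#' spectrum over a window centred on each (sub-bin-interpolated) peak
#' position — the symmetric integral cancels the dispersive component —
#' and the linear phase model is fitted by weighted circular regression
#' (a grid over the first-order term with the zero-order term in closed
#' form). Second, the estimate is polished by a bounded Nelder-Mead search
#' on the criterion: the integrated squared negative real part (scaled).
#' The negativity criterion alone is degenerate on sparse spectra (a phase
#' roll vanishing at every peak also scores zero), which is why the
#' peak-regression stage determines the solution and the criterion only
#' refines it locally. The identity correction is retained whenever it
#' scores no worse, so the criterion never increases.
#'
#' @param spec An `mrs_spectrum`.
#' @param basis Optional `mrs_basis`. When supplied, phasing is model-based:
#'   the criterion is the residual sum of squares of a non-negative
#'   linear-combination fit of the basis to the phased real part, which
#'   pins both phase orders sharply (a dispersive component cannot be
#'   mimicked by non-negative absorption shapes). This is the most accurate
#'   mode and the one the quantification pipeline uses.
#' @param window_ppm Length-2 ppm window over which phasing is evaluated.
#' @param pivot_ppm First-order phase pivot.
#' @param max_phi1 Largest first-order magnitude considered (deg/ppm).
#' @return A list: `spectrum` (phased), `phi0_deg`, `phi1_deg_per_ppm`,
#'   `criterion` (criterion value at the optimum).
#' @export
auto_phase <- function(spec, basis = NULL, window_ppm = c(0.5, 4.2),
                       pivot_ppm = 3.0, max_phi1 = 45) {
  if (all(Mod(spec$values) == 0)) abort("cannot phase an all-zero spectrum")
  idx <- ppm_window(spec, window_ppm[1], window_ppm[2])
  v <- spec$values[idx]
  ppm <- spec$ppm[idx]
  h <- max(Mod(v))
  negcrit <- function(par) {
    re <- Re(apply_phase(v, ppm, par[1], par[2], pivot_ppm))
    sum(pmin(re, 0)^2) / h^2
  }

  if (!is.null(basis)) {
    base_fids <- basis_fid_matrix(basis, spec$params)
    A <- lc_design(base_fids, spec$params, length(spec$values), idx, 0, 0)
    crit <- function(par) {
      re <- Re(apply_phase(v, ppm, par[1], par[2], pivot_ppm))
      a <- pracma::lsqnonneg(A, re)$x
      sum((re - A %*% a)^2)
    }
    best <- NULL
    for (p0 in seq(-180, 165, by = 15)) {
      for (p1 in c(-10, -5, 0, 5, 10)) {
        val <- crit(c(p0, p1))
        if (is.null(best) || val < best$val) best <- list(val = val, par = c(p0, p1))
      }
    }
    fit <- optim(best$par, crit, method = "Nelder-Mead",
                 control = list(maxit = 600, reltol = 1e-12))
    fit <- optim(fit$par, crit, method = "Nelder-Mead",
                 control = list(maxit = 600, reltol = 1e-12))
    cand <- fit$par
    crit_out <- crit
  } else {
    # stage 1: peak-phase circular regression
    pk <- phase_peak_estimates(v, ppm)
    best <- list(sc = -Inf, p0 = 0, p1 = 0)
    for (p1 in seq(-max_phi1, max_phi1, by = 0.25)) {
      z <- sum(pk$w * exp(1i * (pk$phase - p1 * (pk$ppm - pivot_ppm) * pi / 180)))
      if (Mod(z) > best$sc) {
        best <- list(sc = Mod(z), p0 = Arg(z) * 180 / pi, p1 = p1)
      }
    }
    # stage 2: local polish on the negativity criterion
    fit <- optim(c(best$p0, best$p1), negcrit, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10))
    cand <- fit$par
    # never move far from the peak-regression solution
    cand[1] <- best$p0 + max(min(cand[1] - best$p0, 6), -6)
    cand[2] <- best$p1 + max(min(cand[2] - best$p1, 3), -3)
    if (negcrit(c(0, 0)) <= negcrit(cand)) cand <- c(0, 0)
    crit_out <- negcrit
  }

  phi0 <- ((cand[1] + 180) %% 360) - 180
  phi1 <- cand[2]
  out <- spec
  out$values <- apply_phase(spec$values, spec$ppm, phi0, phi1, pivot_ppm)
  list(
    spectrum = out, phi0_deg = phi0, phi1_deg_per_ppm = phi1,
    criterion = crit_out(c(phi0, phi1))
  )
}

# Phases of the strongest resolved peaks, measured by symmetric complex
# integrals around sub-bin-interpolated peak centres. A complex background,
# linearly interpolated between the window edges, is subtracted first: it
# carries the slowly varying dispersive tails of distant peaks (and the
# first-point pedestal), which would otherwise bias the phase badly.
phase_peak_estimates <- function(v, ppm, half_width_ppm = 0.15,
                                 max_peaks = 10, min_sep_ppm = 0.12) {
  mag <- Mod(v)
  n <- length(v)
  thr <- 0.1 * max(mag)
  cand <- which(mag > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[mag[cand] >= mag[cand - 1] & mag[cand] >= mag[cand + 1]]
  cand <- cand[order(mag[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in cand) {
    if (all(abs(ppm[i] - ppm[sel]) > min_sep_ppm)) sel <- c(sel, i)
    if (length(sel) >= max_peaks) break
  }
  centre <- vapply(sel, function(i) {
    # parabolic sub-bin interpolation of the magnitude maximum
    y1 <- mag[i - 1]; y2 <- mag[i]; y3 <- mag[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
    ppm[i] + max(min(delta, 0.5), -0.5) * (ppm[2] - ppm[1])
  }, numeric(1))
  phase <- vapply(seq_along(sel), function(k) {
    w <- which(abs(ppm - centre[k]) <= half_width_ppm)
    bg <- seq(v[w[1]], v[w[length(w)]], length.out = length(w))
    Arg(sum(v[w] - bg))
  }, numeric(1))
  list(ppm = centre, phase = phase, w = mag[sel])
}

# magnitude maximum of the water resonance, 4.2-5.2 ppm
water_peak_magnitude <- function(water_spec, window_ppm = c(4.2, 5.2)) {
  idx <- ppm_window(water_spec, window_ppm[1], window_ppm[2])
  if (!length(idx)) abort("water window outside the spectrum axis")
  max(Mod(water_spec$values[idx]))
}

#' Normalize a spectrum to the unsuppressed water peak
#'
#' Divides the spectrum by the magnitude maximum of the water-reference
#' spectrum within 4.2-5.2 ppm, tagging the result `water_normalized`. The
#' water peak must exceed 5 times the reference noise SD (estimated from the
#' outer 5% of the reference axis) to count as detectable.
#'
#' @param spec `mrs_spectrum` (raw).
#' @param water_spec `mrs_spectrum` of the unsuppressed water reference.
#' @return Normalized `mrs_spectrum`.
#' @export
water_normalize <- function(spec, water_spec) {
  if (spec$normalization == "water_normalized") {
    abort("spectrum is already water-normalized")
  }
  peak <- water_peak_magnitude(water_spec)
  n <- length(water_spec$values)
  k <- max(2, floor(0.05 * n))
  tail_vals <- c(Re(water_spec$values[1:k]), Re(water_spec$values[(n - k + 1):n]))
  noise <- sd(tail_vals)
  if (is.finite(noise) && noise > 0 && peak <= 5 * noise) {
    abort("water peak not detectable (peak <= 5 x noise SD)")
  }
  out <- spec
  out$values <- spec$values / peak
  out$normalization <- "water_normalized"
  out
}

#' Convert between ppm and Hz offsets
#'
#' @param ppm,hz Values to convert.
#' @param params Acquisition parameters supplying the transmitter frequency.
#' @return Numeric vector.
#' @export
ppm_to_hz <- function(ppm, params) (ppm - WATER_PPM) * params$transmitter_mhz

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, params) WATER_PPM + hz / params$transmitter_mhz
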