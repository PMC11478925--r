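#' Configuration for linear-combination model fitting
#'
#' @param window_ppm Fit window (default 0.2-4.0 ppm, excluding residual
#'   water).
#' @param knot_spacing_ppm Spline-baseline knot spacing (0.15 ppm default,
#'   the conventional knot distance for short-echo baselines).
#' @param baseline Logical; include the spline baseline.
#' @param baseline_lambda Roughness-penalty weight for the baseline; `NULL`
#'   selects it by generalized cross-validation over a log-spaced grid, with
#'   a fixed fallback of 1 if GCV is degenerate.
#' @param fit_shift,max_shift_ppm Optimize a global frequency shift of the
#'   basis, bounded by `max_shift_ppm`.
#' @param fit_damping,max_damp_hz Optimize a global additional Lorentzian
#'   broadening of the basis, bounded by `max_damp_hz`.
#' @param nonneg Constrain component amplitudes to be non-negative (the
#'   negative creatine-methylene singlet keeps its fixed negative shape and
#'   a non-negative multiplier).
#' @return A `mrs_fit_config` list.
#' @export
fit_config <- function(window_ppm = c(0.2, 4.0), knot_spacing_ppm = 0.15,
                       baseline = TRUE, baseline_lambda = NULL,
                       fit_shift = TRUE, max_shift_ppm = 0.05,
                       fit_damping = TRUE, max_damp_hz = 5,
                       nonneg = TRUE) {
  stopifnot(knot_spacing_ppm > 0, window_ppm[1] < window_ppm[2])
  structure(list(
    window_ppm = window_ppm, knot_spacing_ppm = knot_spacing_ppm,
    baseline = baseline, baseline_lambda = baseline_lambda,
    fit_shift = fit_shift, max_shift_ppm = max_shift_ppm,
    fit_damping = fit_damping, max_damp_hz = max_damp_hz,
    nonneg = nonneg
  ), class = "mrs_fit_config")
}

# real-part basis design matrix on the window, for a rigid shift/broadening
lc_design <- function(base_fids, params, m_total, idx, shift_ppm, damp_hz) {
  if (shift_ppm != 0 || damp_hz != 0) {
    t <- acq_time_axis(params)
    phasor <- exp((2i * pi * shift_ppm * params$transmitter_mhz - pi * damp_hz) * t)
    base_fids <- base_fids * phasor  # recycles down columns
  }
  if (m_total > nrow(base_fids)) {
    base_fids <- rbind(
      base_fids,
      matrix(0 + 0i, m_total - nrow(base_fids), ncol(base_fids))
    )
  }
  sp <- stats::mvfft(base_fids) * params$dwell_s
  sp <- apply(sp, 2, fftshift_vec)
  Re(sp[idx, , drop = FALSE])
}

second_diff_penalty <- function(q) {
  if (q < 3) return(diag(0, q))
  D <- diff(diag(q), differences = 2)
  crossprod(D)
}

# solve min ||y - A a - S b||^2 + lambda b'Pb, a >= 0 (optional)
lc_inner_solve <- function(y, A, S, P, lambda, nonneg) {
  q <- if (is.null(S)) 0 else ncol(S)
  if (q > 0) {
    G <- crossprod(S) + lambda * P
    R <- tryCatch(chol(G), error = function(e) chol(G + 1e-10 * max(diag(G)) * diag(q)))
    solveG <- function(Z) backsolve(R, forwardsolve(t(R), crossprod(S, Z)))
    My <- y - S %*% solveG(y)
    MA <- A - S %*% solveG(A)
  } else {
    My <- y
    MA <- A
  }
  if (nonneg) {
    a <- pracma::lsqnonneg(as.matrix(MA), as.numeric(My))$x
  } else {
    a <- qr.solve(MA, My)
  }
  a <- as.numeric(a)
  b <- if (q > 0) as.numeric(solveG(y - A %*% a)) else numeric(0)
  baseline <- if (q > 0) as.numeric(S %*% b) else numeric(length(y))
  fitted_signal <- as.numeric(A %*% a)
  resid <- y - fitted_signal - baseline
  list(a = a, b = b, baseline = baseline, fitted_signal = fitted_signal,
       resid = resid, rss = sum(resid^2))
}

# GCV choice of the baseline penalty on the unconstrained ridge problem
select_lambda_gcv <- function(y, A, S, P, grid = 10^seq(-2, 4, by = 1)) {
  X <- cbind(A, S)
  p <- ncol(A)
  q <- ncol(S)
  Pfull <- matrix(0, p + q, p + q)
  Pfull[(p + 1):(p + q), (p + 1):(p + q)] <- P
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  n <- length(y)
  best <- NULL
  for (lam in grid) {
    H <- tryCatch(solve(XtX + lam * Pfull), error = function(e) NULL)
    if (is.null(H)) next
    beta <- H %*% Xty
    fit <- X %*% beta
    edf <- sum(diag(X %*% H %*% t(X)))
    rss <- sum((y - fit)^2)
    denom <- (n - edf)
    if (denom <= 0) next
    gcv <- n * rss / denom^2
    if (is.null(best) || gcv < best$gcv) best <- list(gcv = gcv, lambda = lam)
  }
  if (is.null(best)) 1 else best$lambda
}

#' Fit a spectrum as a linear combination of basis components
#'
#' Minimizes the squared distance between the real part of the spectrum and
#' a non-negative combination of basis component spectra plus a penalised
#' cubic B-spline baseline (knots every `knot_spacing_ppm`), over the fit
#' window. A global frequency shift and a global Lorentzian broadening of
#' the basis are optimised in an outer bounded search; the amplitudes are
#' solved as a constrained linear subproblem (non-negative least squares
#' after projecting out the baseline) inside each outer evaluation.
#'
#' @param spec A phased `mrs_spectrum`.
#' @param basis A `mrs_basis`.
#' @param cfg A [fit_config()].
#' @return An `mrs_quant` object. Its `components` tibble holds per-component
#'   amplitudes (instrument units), CRLB percentages and (after
#'   [water_reference_scale()]) concentrations in mM; diagnostics include the
#'   fitted baseline and residual on the window, the noise SD estimate,
#'   linewidth (FWHM, ppm) and SNR.
#' @export
fit_linear_combination <- function(spec, basis, cfg = fit_config()) {
  if (cfg$window_ppm[1] < min(spec$ppm) || cfg$window_ppm[2] > max(spec$ppm)) {
    abort("fit window lies outside the spectrum axis")
  }
  idx <- ppm_window(spec, cfg$window_ppm[1], cfg$window_ppm[2])
  y <- Re(spec$values[idx])
  ppm_w <- spec$ppm[idx]
  params <- spec$params
  m_total <- length(spec$values)

  base_fids <- basis_fid_matrix(basis, params)
  S <- NULL
  P <- NULL
  if (cfg$baseline) {
    knots <- seq(cfg$window_ppm[1] + cfg$knot_spacing_ppm,
                 cfg$window_ppm[2] - cfg$knot_spacing_ppm / 2,
                 by = cfg$knot_spacing_ppm)
    S <- splines::bs(ppm_w, knots = knots, degree = 3, intercept = TRUE,
                     Boundary.knots = cfg$window_ppm)
    S <- matrix(as.numeric(S), nrow = length(ppm_w))
    P <- second_diff_penalty(ncol(S))
  }

  A0 <- lc_design(base_fids, params, m_total, idx, 0, 0)
  lambda <- cfg$baseline_lambda
  if (cfg$baseline && is.null(lambda)) {
    lambda <- select_lambda_gcv(y, A0, S, P)
  }
  if (is.null(lambda)) lambda <- 0

  objective <- function(par) {
    sh <- if (cfg$fit_shift) par[["shift"]] else 0
    dm <- if (cfg$fit_damping) par[["damp"]] else 0
    A <- lc_design(base_fids, params, m_total, idx, sh, dm)
    lc_inner_solve(y, A, S, P, lambda, cfg$nonneg)$rss
  }

  shift <- 0
  damp <- 0
  converged <- TRUE
  if (cfg$fit_shift || cfg$fit_damping) {
    par0 <- c(shift = 0, damp = 0)[c(cfg$fit_shift, cfg$fit_damping)]
    lower <- c(shift = -cfg$max_shift_ppm, damp = 0)[c(cfg$fit_shift, cfg$fit_damping)]
    upper <- c(shift = cfg$max_shift_ppm, damp = cfg$max_damp_hz)[c(cfg$fit_shift, cfg$fit_damping)]
    obj_named <- function(p) {
      names(p) <- names(par0)
      objective(p)
    }
    opt <- optim(par0, obj_named, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = 60, factr = 1e9,
                                parscale = pmax(abs(upper - lower), 1e-3)))
    converged <- opt$convergence == 0
    pp <- opt$par
    names(pp) <- names(par0)
    if (cfg$fit_shift) shift <- pp[["shift"]]
    if (cfg$fit_damping) damp <- pp[["damp"]]
  }

  A <- lc_design(base_fids, params, m_total, idx, shift, damp)
  sol <- lc_inner_solve(y, A, S, P, lambda, cfg$nonneg)
  noise_sd <- sd(diff(sol$resid)) / sqrt(2)

  # linewidth of the tallest single fitted metabolite resonance, so FWHM
  # reflects line broadening rather than multiplet overlap or MM/lipid humps
  met_idx <- which(basis$class == "metabolite")
  peak_heights <- vapply(met_idx, function(j) max(A[, j] * sol$a[j]), 0)
  j_star <- met_idx[which.max(peak_heights)]
  pk_star <- basis$peaks[[j_star]]
  pk_star <- pk_star[which.max(abs(pk_star$amp)), , drop = FALSE]
  single_fid <- matrix(component_fid(pk_star, params,
                                     shift_ppm = shift,
                                     extra_damp_hz = damp), ncol = 1)
  single_curve <- lc_design(single_fid, params, m_total, idx, 0, 0)[, 1]
  fwhm_ppm <- estimate_fwhm(ppm_w, single_curve)
  # data-based SNR: tallest point above the median level (a robust baseline
  # stand-in) over twice the noise SD
  snr <- if (noise_sd > 0) (max(y) - median(y)) / (2 * noise_sd) else Inf

  # jacobian of the model wrt all free parameters at the solution
  J <- A
  extra <- NULL
  if (cfg$fit_shift) {
    h <- 1e-4
    dA <- (lc_design(base_fids, params, m_total, idx, shift + h, damp) -
             lc_design(base_fids, params, m_total, idx, shift - h, damp)) / (2 * h)
    extra <- cbind(extra, dA %*% sol$a)
  }
  if (cfg$fit_damping) {
    h <- 1e-3
    dA <- (lc_design(base_fids, params, m_total, idx, shift, damp + h) -
             lc_design(base_fids, params, m_total, idx, shift, pmax(damp - h, 0))) /
      (h + min(damp, h))
    extra <- cbind(extra, dA %*% sol$a)
  }
  if (!is.null(S)) J <- cbind(J, S)
  if (!is.null(extra)) J <- cbind(J, extra)
  pen <- NULL
  if (!is.null(S)) {
    pen <- matrix(0, ncol(J), ncol(J))
    sp_idx <- ncol(A) + seq_len(ncol(S))
    pen[sp_idx, sp_idx] <- lambda * P
  }

  # noiseless fits get a vanishing noise floor so CRLBs tend to zero while
  # non-identifiable components still flag 999
  crlb <- compute_crlb(J, sol$a, max(noise_sd, 1e-12),
                       amp_idx = seq_len(ncol(A)), penalty = pen)

  comps <- tibble(
    component = basis$component,
    class = basis$class,
    group = basis$group,
    amplitude = sol$a,
    crlb_pct = crlb,
    concentration = NA_real_
  )
  structure(list(
    components = comps,
    baseline = sol$baseline,
    fitted = sol$fitted_signal + sol$baseline,
    fitted_signal = sol$fitted_signal,
    residual = sol$resid,
    ppm = ppm_w,
    window_idx = idx,
    noise_sd = noise_sd,
    fwhm_ppm = fwhm_ppm,
    snr = snr,
    shift_ppm = shift,
    damp_hz = damp,
    lambda = lambda,
    rss = sol$rss,
    converged = converged,
    jacobian = J,
    n_amp = ncol(A),
    water_scaled = FALSE,
    spectrum_normalization = spec$normalization,
    params = params
  ), class = "mrs_quant")
}

estimate_fwhm <- function(ppm, signal) {
  if (max(signal) <= 0) return(NA_real_)
  i0 <- which.max(signal)
  half <- signal[i0] / 2
  left <- NA_real_
  right <- NA_real_
  for (i in seq(i0, 2)) {
    if (signal[i - 1] <= half) {
      left <- ppm[i - 1] + (ppm[i] - ppm[i - 1]) *
        (half - signal[i - 1]) / (signal[i] - signal[i - 1])
      break
    }
  }
  for (i in seq(i0, length(signal) - 1)) {
    if (signal[i + 1] <= half) {
      right <- ppm[i] + (ppm[i + 1] - ppm[i]) *
        (half - signal[i]) / (signal[i + 1] - signal[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) NA_real_ else right - left
}

#' @export
print.mrs_quant <- function(x, ...) {
  cat(sprintf(
    "<mrs_quant> %d components, noise SD %.3g, FWHM %.3g ppm, SNR %.1f%s\n",
    nrow(x$components), x$noise_sd, x$fwhm_ppm, x$snr,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}

#' @export
tidy.mrs_quant <- function(x, ...) x$components

#' @export
glance.mrs_quant <- function(x, ...) {
  tibble(
    noise_sd = x$noise_sd, fwhm_ppm = x$fwhm_ppm, snr = x$snr,
    shift_ppm = x$shift_ppm, damp_hz = x$damp_hz, lambda = x$lambda,
    rss = x$rss, converged = x$converged
  )
}

#' Cramer-Rao lower bounds for fitted amplitudes
#'
#' Computes `100 * sqrt([(J'J)^-1]_cc) * noise_sd / a_c` for each amplitude
#' parameter, marginalised over all free parameters (baseline coefficients
#' and nonlinear parameters included in the jacobian). Undefined or infinite
#' bounds (zero amplitude, non-identifiable columns) are reported as 999.
#'
#' @param jacobian Jacobian of the model with respect to all free parameters
#'   at the solution (columns: amplitudes first, then the rest, unless
#'   `amp_idx` says otherwise).
#' @param amplitudes Fitted amplitudes.
#' @param noise_sd Noise standard deviation of the fitted data points.
#' @param amp_idx Column indices of the amplitude parameters in `jacobian`.
#' @param penalty Optional quadratic-penalty matrix (same dimension as the
#'   parameter vector) added to the information matrix, so that the bound
#'   reflects the regularised estimator actually used (the baseline
#'   roughness penalty in the default fit).
#' @return Numeric vector of CRLB percentages (capped at 999).
#' @export
compute_crlb <- function(jacobian, amplitudes, noise_sd,
                         amp_idx = seq_along(amplitudes), penalty = NULL) {
  stopifnot(noise_sd > 0, length(amp_idx) == length(amplitudes))
  Fi <- crossprod(jacobian)
  if (!is.null(penalty)) Fi <- Fi + penalty
  # equilibrate so that near-collinearity of a component pair inflates only
  # that pair's variance instead of destabilising the whole inverse
  d <- sqrt(diag(Fi))
  d[d <= 0] <- 1
  Fs <- Fi / tcrossprod(d)
  e <- eigen(Fs, symmetric = TRUE)
  tol <- max(e$values) * 1e-12
  singular <- min(e$values) < tol
  cov_s <- if (singular) {
    warn("singular information matrix; using pseudo-inverse")
    MASS::ginv(Fs)
  } else {
    solve(Fs)
  }
  v <- diag(cov_s)[amp_idx] / d[amp_idx]^2
  if (singular) {
    # parameters with weight in the null space are non-identifiable
    null_vecs <- e$vectors[, e$values < tol, drop = FALSE]
    bad <- rowSums(null_vecs^2) > 1e-4
    v[bad[amp_idx]] <- Inf
  }
  out <- 100 * sqrt(pmax(v, 0)) * noise_sd / abs(amplitudes)
  out[!is.finite(out) | amplitudes <= 0] <- 999
  pmin(out, 999)
}

#' Scale fitted amplitudes to concentrations via the water reference
#'
#' `conc_c = a_c / A_water * water_conc_mm * proton_correction_c`, where
#' `A_water` is the water amplitude recovered from the unsuppressed
#' reference spectrum (the integral of the complex spectrum over the whole
#' axis, which equals the first time-domain sample and is insensitive to
#' linewidth). Relaxation correction is not applied; the default proton
#' correction is 1 (the synthetic basis is amplitude-calibrated per mM).
#'
#' @param result An `mrs_quant`.
#' @param water_spec `mrs_spectrum` of the unsuppressed water reference
#'   (raw, not apodized).
#' @param water_conc_mm Assumed water concentration in mM (35880 default).
#' @param proton_correction Scalar or per-component named vector.
#' @return The `mrs_quant` with the `concentration` column filled in (mM).
#' @export
water_reference_scale <- function(result, water_spec, water_conc_mm = 35880,
                                  proton_correction = 1) {
  df_hz <- diff(water_spec$ppm[1:2]) * water_spec$params$transmitter_mhz
  a_water <- Mod(sum(water_spec$values) * df_hz)
  if (!is.finite(a_water) || a_water <= 0) {
    abort("water amplitude must be positive")
  }
  pc <- rep(1, nrow(result$components))
  if (length(proton_correction) == 1) {
    pc[] <- proton_correction
  } else {
    i <- match(result$components$component, names(proton_correction))
    pc[!is.na(i)] <- proton_correction[i[!is.na(i)]]
  }
  result$components$concentration <-
    result$components$amplitude / a_water * water_conc_mm * pc
  result$water_scaled <- TRUE
  result$a_water <- a_water
  result
}

#' Collapse the 26-component fit into the 19 analysis variables
#'
#' The 16 metabolite concentrations pass through unchanged; the nine
#' macromolecule/lipid concentrations are summed into `MMLip09`, `MMLip13`
#' and `MMLip20` by group tag; the negative creatine-methylene reference is
#' excluded. A group's CRLB is the minimum of its members' CRLBs (a group is
#' quantifiable if any member is).
#'
#' @param result An `mrs_quant` with all 26 default components.
#' @param use `"concentration"` (default; requires
#'   [water_reference_scale()] first) or `"amplitude"`.
#' @return A tibble with 19 rows: `feature`, `value`, `crlb_pct`.
#' @export
group_mmlip <- function(result, use = c("concentration", "amplitude")) {
  use <- match.arg(use)
  comps <- result$components
  needed <- c("metabolite", "mmlip")
  if (!all(needed %in% comps$class) || nrow(comps) < 26) {
    abort("result does not contain the full 26-component basis")
  }
  if (use == "concentration" && all(is.na(comps$concentration))) {
    abort("no concentrations present; run water_reference_scale() or use = \"amplitude\"")
  }
  val <- if (use == "concentration") comps$concentration else comps$amplitude
  met <- comps$class == "metabolite"
  out_met <- tibble(
    feature = comps$component[met],
    value = val[met],
    crlb_pct = comps$crlb_pct[met]
  )
  groups <- c("MMLip09", "MMLip13", "MMLip20")
  out_grp <- purrr::map_dfr(groups, function(g) {
    sel <- !is.na(comps$group) & comps$group == g
    if (!any(sel)) abort(paste0("missing MMLip group: ", g))
    tibble(feature = g, value = sum(val[sel]), crlb_pct = min(comps$crlb_pct[sel]))
  })
  bind_rows(out_met, out_grp)
}

#' Preprocess and quantify one subject
#'
#' Convenience wrapper running the full single-subject chain: eddy-current
#' correction against the water reference, Fourier transform, automatic
#' phasing, linear-combination fitting, water-referenced concentration
#' scaling and MMLip grouping.
#'
#' @param fid Water-suppressed `mrs_fid`.
#' @param water_ref Water-reference `mrs_fid`.
#' @param basis Basis set.
#' @param cfg Fit configuration.
#' @return A list: `quant` (`mrs_quant`), `features` (19-row tibble),
#'   `spectrum` (phased `mrs_spectrum`), `water_spectrum`, `phi0_deg`,
#'   `phi1_deg_per_ppm`.
#' @export
quantify_subject <- function(fid, water_ref, basis = build_default_basis(),
                             cfg = fit_config()) {
  fid_ecc <- eddy_current_correct(fid, water_ref)
  spec <- to_spectrum(fid_ecc)
  ph <- auto_phase(spec, basis = basis)
  wspec <- to_spectrum(water_ref)
  q <- fit_linear_combination(ph$spectrum, basis, cfg)
  q <- water_reference_scale(q, wspec)
  list(
    quant = q,
    features = group_mmlip(q),
    spectrum = ph$spectrum,
    water_spectrum = wspec,
    phi0_deg = ph$phi0_deg,
    phi1_deg_per_ppm = ph$phi1_deg_per_ppm
  )
}

#' Subtract the fitted baseline from a spectrum
#'
#' Used before averaging spectra for display: the fitted spline baseline is
#' subtracted from the real part over the fit window (zero outside).
#'
#' @param spec The `mrs_spectrum` that was fitted.
#' @param result The corresponding `mrs_quant`.
#' @return An `mrs_spectrum`.
#' @export
subtract_baseline <- function(spec, result) {
  bl <- numeric(length(spec$values))
  bl[result$window_idx] <- result$baseline
  out <- spec
  out$values <- complex(real = Re(spec$values) - bl, imaginary = Im(spec$values))
  out
}
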