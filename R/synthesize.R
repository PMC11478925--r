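#' Time-domain MR signal (free induction decay)
#'
#' @param values Complex vector of samples.
#' @param params An [acq_params()] object.
#' @param kind `"water_suppressed"` or `"water_reference"`.
#' @return An `mrs_fid` object.
#' @export
mrs_fid <- function(values, params, kind = c("water_suppressed", "water_reference")) {
  kind <- match.arg(kind)
  values <- as.complex(values)
  if (length(values) != params$n_points) {
    abort(sprintf(
      "FID length %d does not match n_points %d",
      length(values), params$n_points
    ))
  }
  structure(
    list(values = values, dwell_s = params$dwell_s, params = params, kind = kind),
    class = "mrs_fid"
  )
}

#' @export
print.mrs_fid <- function(x, ...) {
  cat(sprintf(
    "<mrs_fid> %s, %d complex points, dwell %.3g s\n",
    x$kind, length(x$values), x$dwell_s
  ))
  invisible(x)
}

#' Artifact settings for the forward simulator
#'
#' @param phase0_deg Zero-order phase error in degrees.
#' @param phase1_deg_per_ppm First-order phase error in degrees per ppm
#'   (pivot at 3.0 ppm).
#' @param eddy_amp_rad Amplitude of the exponentially decaying eddy-current
#'   phase distortion, radians at t = 0.
#' @param eddy_tau_ms Decay constant of the eddy-current phase, ms.
#' @param noise_sd Standard deviation of the complex Gaussian noise added to
#'   each of the real and imaginary channels (time domain, instrument units).
#' @return A named list.
#' @export
artifact_settings <- function(phase0_deg = 0, phase1_deg_per_ppm = 0,
                              eddy_amp_rad = 0, eddy_tau_ms = 50,
                              noise_sd = 0) {
  stopifnot(noise_sd >= 0, eddy_tau_ms > 0)
  list(
    phase0_deg = phase0_deg, phase1_deg_per_ppm = phase1_deg_per_ppm,
    eddy_amp_rad = eddy_amp_rad, eddy_tau_ms = eddy_tau_ms,
    noise_sd = noise_sd
  )
}

eddy_phase <- function(t, art) art$eddy_amp_rad * exp(-t / (art$eddy_tau_ms / 1000))

#' Synthesize a water-suppressed FID and its water reference
#'
#' Forward model: the FID is the concentration-weighted sum of the basis
#' component FIDs (each peak a damped complex exponential), multiplied by a
#' common phase factor `exp(i (phi0 + phi_eddy(t)))`, plus complex Gaussian
#' noise. The water reference contains a single water resonance at 4.7 ppm
#' with amplitude equal to the assumed water concentration (so the
#' water-referenced concentration scale is self-consistent), carries the same
#' eddy-current phase, and has noise reduced according to the ratio of
#' averages.
#'
#' @param profile Named numeric vector of concentrations in mM (names must be
#'   basis component names; non-negative).
#' @param basis A [build_default_basis()] object.
#' @param params An [acq_params()] object.
#' @param artifacts An [artifact_settings()] list.
#' @param seed Integer seed; the simulation is bit-reproducible given the seed.
#' @param water_conc_mm Assumed water concentration (mM) setting the water
#'   reference amplitude.
#' @param water_lw_hz Water resonance linewidth, Hz.
#' @return A list with elements `water_suppressed` and `water_reference`,
#'   both `mrs_fid` objects.
#' @export
synthesize_fid <- function(profile, basis, params = acq_params(),
                           artifacts = artifact_settings(), seed = 1,
                           water_conc_mm = 35880, water_lw_hz = 6) {
  if (length(profile)) {
    unknown <- setdiff(names(profile), basis$component)
    if (length(unknown)) {
      abort(paste0("unknown basis component(s): ", paste(unknown, collapse = ", ")))
    }
    if (any(profile < 0)) abort("concentrations must be non-negative")
  }
  t <- acq_time_axis(params)
  fid <- complex(real = numeric(params$n_points))
  for (nm in names(profile)) {
    if (profile[[nm]] == 0) next
    i <- match(nm, basis$component)
    fid <- fid + profile[[nm]] * component_fid(
      basis$peaks[[i]], params,
      phase0_deg = artifacts$phase0_deg
    )
  }
  if (artifacts$phase1_deg_per_ppm != 0) {
    # first-order phase is a continuous frequency-domain ramp (pivot 3 ppm)
    n <- params$n_points
    freq <- (seq_len(n) - 1 - n / 2) * params$bandwidth_hz / n
    ppm_axis <- WATER_PPM + freq / params$transmitter_mhz
    ramp <- exp(1i * artifacts$phase1_deg_per_ppm * (ppm_axis - 3.0) * pi / 180)
    sp <- fftshift_vec(fft(fid))
    fid <- fft(fftshift_vec(sp * ramp), inverse = TRUE) / n
  }
  water_peaks <- tibble(
    ppm = WATER_PPM, amp = 1, lw_hz = water_lw_hz, shape = "lorentzian"
  )
  wref <- water_conc_mm * component_fid(
    water_peaks, params, phase0_deg = artifacts$phase0_deg
  )
  ephi <- exp(1i * eddy_phase(t, artifacts))
  fid <- fid * ephi
  wref <- wref * ephi

  if (artifacts$noise_sd > 0) {
    set.seed(as.integer(seed))
    n <- params$n_points
    fid <- fid + complex(
      real = rnorm(n, sd = artifacts$noise_sd),
      imaginary = rnorm(n, sd = artifacts$noise_sd)
    )
    # same per-average noise, but 8 water averages instead of 128/256
    w_sd <- artifacts$noise_sd * sqrt(params$n_averages / params$n_water_averages)
    wref <- wref + complex(
      real = rnorm(n, sd = w_sd),
      imaginary = rnorm(n, sd = w_sd)
    )
  }
  list(
    water_suppressed = mrs_fid(fid, params, "water_suppressed"),
    water_reference = mrs_fid(wref, params, "water_reference")
  )
}

#' Class-conditional simulation parameters for one tumour type
#'
#' @param tumour_type `"PA"`, `"EP"` or `"MB"`.
#' @param mean Named concentration profile (mM) giving the class mean.
#' @param covariance Covariance matrix over the profiled components
#'   (symmetric positive semidefinite), or `NULL` for a diagonal matrix built
#'   from `cv * mean`.
#' @param cv Coefficient of variation used for the default diagonal
#'   covariance.
#' @param phase0_range_deg,phase1_range_deg_per_ppm,eddy_amp_range_rad,eddy_tau_range_ms
#'   Uniform ranges for the acquisition artifacts.
#' @param noise_sd_range Uniform range for the time-domain noise SD.
#' @return A `mrs_class_params` list.
#' @export
class_params <- function(tumour_type, mean, covariance = NULL, cv = 0.25,
                         phase0_range_deg = c(-30, 30),
                         phase1_range_deg_per_ppm = c(-4, 4),
                         eddy_amp_range_rad = c(0, 1.0),
                         eddy_tau_range_ms = c(20, 80),
                         noise_sd_range = c(2, 4)) {
  stopifnot(tumour_type %in% TUMOUR_TYPES, all(mean >= 0))
  if (is.null(covariance)) {
    covariance <- diag((cv * mean)^2, nrow = length(mean))
    dimnames(covariance) <- list(names(mean), names(mean))
  }
  if (!isSymmetric(unname(covariance))) abort("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) abort("covariance must be positive semidefinite")
  structure(list(
    tumour_type = tumour_type, mean = mean, covariance = covariance,
    phase0_range_deg = phase0_range_deg,
    phase1_range_deg_per_ppm = phase1_range_deg_per_ppm,
    eddy_amp_range_rad = eddy_amp_range_rad,
    eddy_tau_range_ms = eddy_tau_range_ms,
    noise_sd_range = noise_sd_range
  ), class = "mrs_class_params")
}

#' Default class-conditional concentration profiles
#'
#' Mean profiles encode the qualitative patterns that separate the three
#' tumour types at short echo time: medulloblastoma with high total choline
#' (GPC + PCh), taurine present and low myo-inositol; pilocytic astrocytoma
#' with low creatine, prominent lactate and the highest
#' macromolecule/lipid levels; ependymoma with high myo-inositol and
#' creatine and the lowest lipids. Values are plausible short-echo tumour
#' concentrations in mM; no published concentration table is reproduced.
#'
#' @param ... Passed on to [class_params()] (e.g. `noise_sd_range`).
#' @return Named list of `mrs_class_params` for PA, EP and MB.
#' @export
default_class_params <- function(...) {
  mm_low <- c(
    Lip09 = 0.8, MM09 = 1.4, MM12 = 0.9, Lip13a = 1.2, Lip13b = 0.8,
    MM14 = 0.9, MM17 = 1.1, Lip20 = 0.9, MM20 = 1.4, `-CrCH2` = 0.6
  )
  mm_mid <- c(
    Lip09 = 0.9, MM09 = 1.4, MM12 = 1.0, Lip13a = 1.3, Lip13b = 0.9,
    MM14 = 1.0, MM17 = 1.1, Lip20 = 1.0, MM20 = 1.4, `-CrCH2` = 0.6
  )
  mm_high <- c(
    Lip09 = 1.4, MM09 = 1.6, MM12 = 1.2, Lip13a = 2.4, Lip13b = 1.6,
    MM14 = 1.3, MM17 = 1.3, Lip20 = 1.4, MM20 = 1.7, `-CrCH2` = 0.6
  )
  pa <- c(
    Ala = 0.7, Asp = 0.5, Cr = 2.8, Glc = 1.6, Gln = 2.2, Glu = 3.5,
    Gly = 0.8, GPC = 1.2, Gua = 0.7, Ins = 4.2, Lac = 3.8, NAA = 1.8,
    NAAG = 0.3, PCh = 1.0, Scyllo = 0.3, Tau = 0.4, mm_high
  )
  ep <- c(
    Ala = 0.8, Asp = 0.6, Cr = 5.6, Glc = 1.4, Gln = 2.6, Glu = 4.2,
    Gly = 1.2, GPC = 1.6, Gua = 0.8, Ins = 8.5, Lac = 2.2, NAA = 1.2,
    NAAG = 0.3, PCh = 1.2, Scyllo = 0.4, Tau = 0.8, mm_low
  )
  mb <- c(
    Ala = 0.9, Asp = 0.7, Cr = 4.4, Glc = 1.2, Gln = 2.4, Glu = 3.8,
    Gly = 1.6, GPC = 2.6, Gua = 0.8, Ins = 1.6, Lac = 3.0, NAA = 1.0,
    NAAG = 0.3, PCh = 2.4, Scyllo = 0.4, Tau = 5.5, mm_mid
  )
  list(
    PA = class_params("PA", pa, ...),
    EP = class_params("EP", ep, ...),
    MB = class_params("MB", mb, ...)
  )
}

# draw one non-negative profile from the class MVN, resampling negatives
draw_profile <- function(cp, max_attempts = 100) {
  L <- tryCatch(chol(cp$covariance), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen(cp$covariance, symmetric = TRUE)
    L <- t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(cp$covariance)))
  }
  p <- length(cp$mean)
  for (i in seq_len(max_attempts)) {
    x <- as.numeric(cp$mean + t(L) %*% rnorm(p))
    if (all(x >= 0)) {
      names(x) <- names(cp$mean)
      return(x)
    }
  }
  x <- pmax(as.numeric(cp$mean + t(L) %*% rnorm(p)), 0)
  names(x) <- names(cp$mean)
  x
}

#' Sample a synthetic cohort of subjects with simulated spectra
#'
#' Concentration profiles are drawn from each class multivariate normal
#' (truncated at zero by resampling); acquisition artifacts are drawn
#' uniformly within the class ranges; FIDs are synthesized with
#' [synthesize_fid()]. Deterministic for fixed `seed`.
#'
#' @param class_params_list Named list of [class_params()] objects.
#' @param n_per_class Named or positional integer vector of subjects per
#'   class, e.g. `c(PA = 12, EP = 4, MB = 18)`.
#' @param basis Basis set used for synthesis.
#' @param params Acquisition parameters.
#' @param seed Integer seed.
#' @param simulate_fids If `FALSE`, only profiles are drawn (fast cohorts for
#'   classifier work).
#' @return A tibble with one row per subject: `subject`, `tumour_type`,
#'   `profile` (list of named vectors), and, when `simulate_fids = TRUE`,
#'   `fid` and `water_ref` (lists of `mrs_fid`), `noise_sd`.
#' @export
sample_cohort <- function(class_params_list, n_per_class, basis = build_default_basis(),
                          params = acq_params(), seed = 1, simulate_fids = TRUE) {
  stopifnot(all(n_per_class >= 1))
  if (is.null(names(n_per_class))) {
    names(n_per_class) <- names(class_params_list)[seq_along(n_per_class)]
  }
  set.seed(as.integer(seed))
  rows <- list()
  k <- 0
  for (cls in names(n_per_class)) {
    cp <- class_params_list[[cls]]
    if (is.null(cp)) abort(paste0("no class_params for ", cls))
    for (i in seq_len(n_per_class[[cls]])) {
      k <- k + 1
      prof <- draw_profile(cp)
      art <- artifact_settings(
        phase0_deg = runif(1, cp$phase0_range_deg[1], cp$phase0_range_deg[2]),
        phase1_deg_per_ppm = runif(1, cp$phase1_range_deg_per_ppm[1],
                                   cp$phase1_range_deg_per_ppm[2]),
        eddy_amp_rad = runif(1, cp$eddy_amp_range_rad[1], cp$eddy_amp_range_rad[2]),
        eddy_tau_ms = runif(1, cp$eddy_tau_range_ms[1], cp$eddy_tau_range_ms[2]),
        noise_sd = runif(1, cp$noise_sd_range[1], cp$noise_sd_range[2])
      )
      row <- list(
        subject = sprintf("S%03d", k), tumour_type = cls,
        profile = list(prof), noise_sd = art$noise_sd
      )
      if (simulate_fids) {
        sim <- synthesize_fid(prof, basis, params, art,
                              seed = sample.int(.Machine$integer.max, 1))
        row$fid <- list(sim$water_suppressed)
        row$water_ref <- list(sim$water_reference)
      }
      rows[[k]] <- row
    }
  }
  out <- tibble(
    subject = vapply(rows, `[[`, "", "subject"),
    tumour_type = vapply(rows, `[[`, "", "tumour_type"),
    profile = lapply(rows, function(r) r$profile[[1]]),
    noise_sd = vapply(rows, `[[`, 0, "noise_sd")
  )
  if (simulate_fids) {
    out$fid <- lapply(rows, function(r) r$fid[[1]])
    out$water_ref <- lapply(rows, function(r) r$water_ref[[1]])
  }
  out
}

#' Simulate a radiologist certainty table for a staged reader study
#'
#' Each rater assigns, for every case and review stage, a certainty
#' percentage to each of the three diagnoses; the three always sum to 100.
#' At the first stage the truth-class certainty is drawn around
#' `base_certainty`; at each later stage it increases stochastically by the
#' rater's stage effect (a median shift in percentage points), and the two
#' remaining certainties are rescaled to preserve the sum.
#'
#' @param truth Character vector of true diagnoses (one per case), values in
#'   `c("PA", "EP", "MB")`.
#' @param stage_effects Either a numeric vector of length 3 (additive median
#'   shift of the truth-class certainty at each stage, first element
#'   conventionally 0) applied to every rater, or a list of such vectors,
#'   one per rater. The defaults emulate reader-study regimes in which the
#'   certainty of the correct diagnosis rises by roughly 8-20 points over
#'   the three stages, with rater-to-rater variation.
#' @param n_raters Number of raters (ignored when `stage_effects` is a list).
#' @param base_certainty Mean truth-class certainty at the first stage.
#' @param base_sd,effect_sd SDs of the first-stage certainty and of the
#'   per-stage stochastic shift.
#' @param seed Integer seed.
#' @return A tibble with columns `rater`, `case`, `stage`, `cert_PA`,
#'   `cert_EP`, `cert_MB`, `truth`.
#' @export
sample_certainty_table <- function(truth,
                                   stage_effects = list(
                                     rad1 = c(0, 9, 7),
                                     rad2 = c(0, 3, 5),
                                     rad3 = c(0, 10, 10)
                                   ),
                                   n_raters = 3,
                                   base_certainty = 55, base_sd = 15,
                                   effect_sd = 7, seed = 1) {
  stopifnot(all(truth %in% TUMOUR_TYPES))
  if (!is.list(stage_effects)) {
    stage_effects <- stats::setNames(
      rep(list(stage_effects), n_raters),
      paste0("rad", seq_len(n_raters))
    )
  }
  for (se in stage_effects) stopifnot(length(se) == length(REVIEW_STAGES))
  set.seed(as.integer(seed))
  out <- list()
  r <- 0
  for (rater in names(stage_effects)) {
    se <- stage_effects[[rater]]
    for (ci in seq_along(truth)) {
      tr <- truth[ci]
      ct <- min(max(base_certainty + rnorm(1, sd = base_sd), 2), 95)
      split <- runif(1, 0.2, 0.8)
      others <- setdiff(TUMOUR_TYPES, tr)
      co <- (100 - ct) * c(split, 1 - split)
      for (si in seq_along(REVIEW_STAGES)) {
        if (si > 1) {
          ct_new <- min(max(ct + se[si] + rnorm(1, sd = effect_sd), 0), 100)
          co <- if (100 - ct > 1e-9) co * (100 - ct_new) / (100 - ct) else
            rep((100 - ct_new) / 2, 2)
          ct <- ct_new
        }
        cert <- stats::setNames(numeric(3), TUMOUR_TYPES)
        cert[tr] <- ct
        cert[others] <- co
        r <- r + 1
        out[[r]] <- tibble(
          rater = rater, case = sprintf("C%03d", ci),
          stage = REVIEW_STAGES[si],
          cert_PA = cert[["PA"]], cert_EP = cert[["EP"]], cert_MB = cert[["MB"]],
          truth = tr
        )
      }
    }
  }
  bind_rows(out)
}
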