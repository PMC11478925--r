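# shared fixtures: all synthetic, built in code

small_params <- function(n_points = 1024) acq_params(n_points = n_points)

# typical short-echo brain-like profile used for recovery benchmarks
benchmark_profile <- function() {
  c(
    Cr = 6, NAA = 9, GPC = 1.5, PCh = 1.0, Ins = 5, Glu = 6, Gln = 3,
    Tau = 1.5, Lac = 1.5, Ala = 0.5, Asp = 1.5, Glc = 1.2, Gly = 0.8,
    Gua = 0.7, NAAG = 1.0, Scyllo = 0.4,
    Lip09 = 1, MM09 = 1.5, MM12 = 1, Lip13a = 1.5, Lip13b = 1,
    MM14 = 1, MM17 = 1.2, Lip20 = 1, MM20 = 1.5, `-CrCH2` = 0.6
  )
}

# a one-component basis holding a single Lorentzian singlet
singlet_basis <- function(ppm = 3.0, amp = 1, lw_hz = 4) {
  tb <- tibble::tibble(
    component = "Singlet", class = "metabolite", group = NA_character_,
    peaks = list(tibble::tibble(ppm = ppm, amp = amp, lw_hz = lw_hz,
                                shape = "lorentzian"))
  )
  mrsdx:::validate_basis(tb)
}

# noiseless FID containing one singlet
singlet_fid <- function(conc = 1, ppm = 3.0, lw_hz = 4,
                        params = small_params()) {
  b <- singlet_basis(ppm = ppm, lw_hz = lw_hz)
  synthesize_fid(c(Singlet = conc), b, params,
                 artifact_settings(), seed = 1)$water_suppressed
}

# 3 well-separated spherical Gaussian classes in feature space
gaussian_cohort <- function(n_per_class, means, sd = 1, seed = 1,
                            labels = c("EP", "MB", "PA")) {
  set.seed(seed)
  p <- length(means[[1]])
  rows <- lapply(seq_along(labels), function(k) {
    X <- matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p)
    X <- sweep(X, 2, means[[k]], "+")
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(p))
    df$tumour_type <- labels[k]
    df
  })
  tibble::as_tibble(do.call(rbind, rows))
}
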