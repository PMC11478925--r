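#' Build the default 26-component spectral basis set
#'
#' The basis contains 16 metabolites, 9 macromolecule/lipid components and a
#' negative creatine-methylene reference singlet at 3.94 ppm, mirroring the
#' composition used for short-echo tumour spectra. Metabolite multiplets are
#' simplified to fixed peak lists (chemical shift, relative amplitude
#' proportional to proton count, linewidth, lineshape); macromolecule and
#' lipid components are broad single resonances. Each macromolecule/lipid
#' component carries a group tag (`MMLip09`, `MMLip13`, `MMLip20`) assigned to
#' the nearest of 0.9, 1.3 and 2.0 ppm, so that grouped concentrations can be
#' formed downstream.
#'
#' @return A `mrs_basis` object: a tibble with one row per component and
#'   columns `component` (name), `class` (`"metabolite"`, `"mmlip"` or
#'   `"reference"`), `group` (MMLip group tag or `NA`) and `peaks`
#'   (list-column of tibbles with `ppm`, `amp`, `lw_hz`, `shape`).
#' @examples
#' b <- build_default_basis()
#' nrow(b)                       # 26
#' sum(b$class == "metabolite")  # 16
#' @export
build_default_basis <- function() {
  pk <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    tibble(
      ppm = as.numeric(m[, 1]),
      amp = as.numeric(m[, 2]),
      lw_hz = as.numeric(m[, 3]),
      shape = c("lorentzian", "gaussian")[as.integer(m[, 4])]
    )
  }
  L <- 1; G <- 2

  metab <- list(
    Ala    = pk(1.47, 3, 4.0, L, 3.77, 1, 4.0, L),
    Asp    = pk(2.65, 1, 5.0, L, 2.80, 1, 5.0, L, 3.89, 1, 5.0, L),
    Cr     = pk(3.03, 3, 4.0, L, 3.91, 2, 4.0, L),
    Glc    = pk(3.43, 2, 5.0, L, 3.80, 2, 5.0, L),
    Gln    = pk(2.13, 2, 6.0, L, 2.45, 2, 6.0, L, 3.75, 1, 5.0, L),
    Glu    = pk(2.08, 2, 6.0, L, 2.35, 2, 6.0, L, 3.74, 1, 5.0, L),
    Gly    = pk(3.55, 2, 4.0, L),
    GPC    = pk(3.21, 9, 4.0, L, 3.68, 2, 5.0, L, 4.31, 2, 5.0, L),
    Gua    = pk(3.78, 2, 4.0, L),
    Ins    = pk(3.52, 4, 4.5, L, 3.61, 2, 4.5, L, 4.05, 1, 4.0, L),
    Lac    = pk(1.31, 3, 4.0, L, 4.10, 1, 4.0, L),
    NAA    = pk(2.01, 3, 4.0, L, 2.49, 1, 5.0, L, 2.67, 1, 5.0, L),
    NAAG   = pk(2.04, 3, 5.0, L),
    PCh    = pk(3.22, 9, 4.0, L, 3.59, 2, 5.0, L, 4.28, 2, 5.0, L),
    Scyllo = pk(3.34, 6, 4.0, L),
    Tau    = pk(3.25, 2, 5.0, L, 3.42, 2, 5.0, L)
  )
  mmlip <- list(
    Lip09  = pk(0.89, 3.0, 25, L),
    MM09   = pk(0.91, 2.0, 30, G),
    MM12   = pk(1.21, 2.0, 30, G),
    Lip13a = pk(1.28, 3.0, 25, L),
    Lip13b = pk(1.30, 2.0, 45, L),
    MM14   = pk(1.43, 2.0, 35, G),
    MM17   = pk(1.67, 2.0, 35, G),
    Lip20  = pk(2.04, 2.0, 30, L),
    MM20   = pk(2.02, 2.5, 35, G)
  )
  crch2 <- list(`-CrCH2` = pk(3.94, -1, 4.0, L))

  rows <- bind_rows(
    tibble(component = names(metab), class = "metabolite", peaks = unname(metab)),
    tibble(component = names(mmlip), class = "mmlip", peaks = unname(mmlip)),
    tibble(component = names(crch2), class = "reference", peaks = unname(crch2))
  )
  rows$group <- NA_character_
  rows$group[rows$class == "mmlip"] <-
    vapply(rows$peaks[rows$class == "mmlip"], mmlip_group_tag, character(1))
  validate_basis(rows[, c("component", "class", "group", "peaks")])
}

# nearest of 0.9 / 1.3 / 2.0 ppm, by amplitude-weighted mean chemical shift
mmlip_group_tag <- function(peaks) {
  centres <- c(MMLip09 = 0.9, MMLip13 = 1.3, MMLip20 = 2.0)
  mean_ppm <- sum(peaks$ppm * abs(peaks$amp)) / sum(abs(peaks$amp))
  names(centres)[which.min(abs(mean_ppm - centres))]
}

validate_basis <- function(x) {
  stopifnot(is.data.frame(x), !anyDuplicated(x$component))
  for (i in seq_len(nrow(x))) {
    p <- x$peaks[[i]]
    stopifnot(nrow(p) >= 1, all(p$ppm >= 0), all(p$ppm <= 4.5))
    if (x$component[i] != "-CrCH2" && any(p$amp < 0)) {
      abort("negative peak amplitude only permitted for -CrCH2")
    }
  }
  structure(as_tibble(x), class = c("mrs_basis", class(as_tibble(x))))
}

#' @export
print.mrs_basis <- function(x, ...) {
  cat(sprintf(
    "<mrs_basis> %d components (%d metabolite, %d MM/lipid, %d reference)\n",
    nrow(x), sum(x$class == "metabolite"), sum(x$class == "mmlip"),
    sum(x$class == "reference")
  ))
  NextMethod()
}

basis_component_names <- function(basis) basis$component

# Complex FID for one basis component at unit concentration.
# shift_ppm / extra_damp_hz apply a rigid frequency shift and additional
# Lorentzian broadening to the whole component.
component_fid <- function(peaks, params, shift_ppm = 0, extra_damp_hz = 0,
                          phase0_deg = 0, phase1_deg_per_ppm = 0,
                          phase1_pivot_ppm = 3.0) {
  t <- acq_time_axis(params)
  f0 <- params$transmitter_mhz  # Hz per ppm
  out <- complex(real = numeric(params$n_points))
  for (j in seq_len(nrow(peaks))) {
    df_hz <- (peaks$ppm[j] + shift_ppm - WATER_PPM) * f0
    decay <- switch(peaks$shape[j],
      lorentzian = exp(-pi * peaks$lw_hz[j] * t),
      gaussian = exp(-(pi * peaks$lw_hz[j] * t)^2 / (4 * log(2))),
      abort(paste0("unknown lineshape: ", peaks$shape[j]))
    )
    ph <- (phase0_deg + phase1_deg_per_ppm *
             (peaks$ppm[j] - phase1_pivot_ppm)) * pi / 180
    out <- out + peaks$amp[j] *
      exp(1i * (2 * pi * df_hz * t + ph)) * decay
  }
  if (extra_damp_hz != 0) out <- out * exp(-pi * extra_damp_hz * t)
  out
}

# matrix of unit-concentration component FIDs, one column per component
basis_fid_matrix <- function(basis, params) {
  vapply(
    basis$peaks,
    function(p) component_fid(p, params),
    complex(params$n_points)
  )
}
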