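# Modified Beer-Lambert model shared by the simulator (forward direction)
# and the preprocessing chain (inverse direction). Keeping one set of
# constants guarantees the forward model is the exact inverse of mbll().

# Molar extinction coefficients, cm^-1 / (mol/L), log10 convention
# (Gratzer/Prahl compilation). Rows are wavelengths, columns [HbO, HbR].
EXTINCTION_TABLE <- list(
  "690" = c(hbo = 276.00, hbr = 2051.96),
  "760" = c(hbo = 586.00, hbr = 1548.52),
  "830" = c(hbo = 974.00, hbr = 693.04),
  "850" = c(hbo = 1058.00, hbr = 691.32)
)

extinction_matrix <- function(wavelengths) {
  rows <- lapply(wavelengths, function(wl) {
    key <- as.character(round(wl))
    if (!key %in% names(EXTINCTION_TABLE)) {
      stop_config(sprintf(
        "no bundled extinction coefficients for %g nm (have: %s); supply them in mbll_params()",
        wl, paste(names(EXTINCTION_TABLE), collapse = ", ")))
    }
    EXTINCTION_TABLE[[key]]
  })
  e <- do.call(rbind, rows)
  dimnames(e) <- list(paste0(wavelengths, "nm"), c("HbO", "HbR"))
  e
}

#' Parameters of the modified Beer-Lambert inversion
#'
#' The modified Beer-Lambert law relates the optical-density change at
#' wavelength lambda to the chromophore concentration changes:
#' \deqn{\Delta OD(\lambda) = \ln(10)\, d\, DPF(\lambda)
#'   [\epsilon_{HbO}(\lambda) \Delta HbO + \epsilon_{HbR}(\lambda) \Delta HbR]}
#' with source-detector separation `d` (cm), differential pathlength factor
#' `DPF`, and log10-convention molar extinction coefficients `epsilon`
#' (cm^-1 M^-1). Inverting the 2x2 system per channel yields `(dHbO, dHbR)`
#' in mol/L, reported in micromolar.
#'
#' @param wavelengths Two wavelengths in nm; extinction coefficients are
#'   looked up in the bundled table unless `extinction` is given.
#' @param extinction Optional 2x2 matrix (wavelength x `[HbO, HbR]`),
#'   cm^-1 M^-1, log10 convention.
#' @param dpf Differential pathlength factor per wavelength (recycled to
#'   length 2). Default 6.0, a standard adult-head value.
#' @param separation_cm Source-detector separation per channel in cm, or a
#'   scalar applied to all channels. Default 3.0.
#' @param baseline_window Sample range (length-2 integer) used as the
#'   reference-intensity window for the optical-density step; default the
#'   first 10 s at the recording's sampling rate.
#' @return An `mbll_params` list.
#' @export
mbll_params <- function(wavelengths = c(690, 830), extinction = NULL,
                        dpf = 6.0, separation_cm = 3.0,
                        baseline_window = NULL) {
  if (is.null(extinction)) extinction <- extinction_matrix(wavelengths)
  extinction <- as.matrix(extinction)
  assert_that(all(dim(extinction) == c(2L, 2L)),
              "extinction must be a 2x2 matrix (wavelength x chromophore)")
  assert_that(kappa_cond(extinction) < 1e12,
              "extinction matrix is singular (chromophores not separable)")
  dpf <- rep_len(as.numeric(dpf), 2L)
  assert_that(all(dpf > 0), "DPF must be positive")
  assert_that(all(separation_cm > 0), "separation must be positive")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 dpf = dpf, separation_cm = separation_cm,
                 baseline_window = baseline_window),
            class = "mbll_params")
}

kappa_cond <- function(m) {
  s <- svd(m, nu = 0, nv = 0)$d
  if (min(s) == 0) Inf else max(s) / min(s)
}

# Per-channel pathlength-scaled extinction system:
# od[, ch, wl] = A(wl, :) %*% c(dHbO, dHbR) * sep[ch], A = ln10 * dpf * eps.
mbll_system <- function(params, n_channels) {
  sep <- rep_len(params$separation_cm, n_channels)
  a <- log(10) * params$dpf * params$extinction  # 2x2, rows = wavelengths
  list(a = a, sep = sep)
}

#' Forward Beer-Lambert model: hemoglobin to optical density
#'
#' Maps concentration changes (uM) to optical-density changes per
#' wavelength. This is the exact inverse of [mbll()] and is used by the
#' simulator to turn injected hemodynamics into raw light intensities.
#'
#' @param hb_um Array `time x channels x 2` (`[HbO, HbR]`), uM.
#' @param params An [mbll_params()].
#' @return Array `time x channels x 2` of OD changes (wavelength axis).
#' @export
forward_mbll <- function(hb_um, params = mbll_params()) {
  d <- dim(hb_um)
  sys <- mbll_system(params, d[2])
  hb_m <- matrix(hb_um, ncol = 2L) * 1e-6  # mol/L, rows = time*channel
  od_tc <- hb_m %*% t(sys$a)               # columns = wavelengths
  od <- array(od_tc, c(d[1], d[2], 2L))
  od * rep(sys$sep, each = d[1])           # scale channel-wise by separation
}
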