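#' Assemble a broadened ensemble spectrum from vertical excitations
#'
#' Nuclear-ensemble spectrum: each excitation line (energy E_i in eV,
#' oscillator strength f_i) contributes a normalised Gaussian of the
#' given full width at half maximum, and the spectrum is the
#' f-weighted mean over the ensemble,
#' I(E) = (1/N) * sum_i f_i * G(E - E_i; fwhm).
#' With this normalisation the integral over an unbounded grid equals
#' the mean oscillator strength.
#'
#' @param records data.frame with columns `energy_eV` (> 0) and
#'   `osc_strength` (>= 0); extra columns (isomer, features) are ignored
#' @param fwhm Gaussian kernel full width at half maximum, eV
#'   (default 0.15)
#' @param grid_from,grid_to,grid_by energy grid, eV (default 1.5-4.5 at
#'   0.002)
#' @return an `ensemble_spectrum`: list with `energy_eV`, `intensity`,
#'   `n_records`, `broadening_fwhm`, `shift_eV` (0 on assembly)
#' @examples
#' rec <- data.frame(energy_eV = 2.7605, osc_strength = 0.1)
#' sp <- assemble_spectrum(rec)
#' @export
assemble_spectrum <- function(records, fwhm = 0.15,
                              grid_from = 1.5, grid_to = 4.5,
                              grid_by = 0.002) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame")
  if (!all(c("energy_eV", "osc_strength") %in% names(records)))
    stop("`records` needs `energy_eV` and `osc_strength` columns")
  if (!is.numeric(fwhm) || fwhm <= 0) stop("`fwhm` must be > 0")
  E <- records$energy_eV
  f <- records$osc_strength
  if (any(!is.finite(E)) || any(E <= 0)) stop("excitation energies must be > 0")
  if (any(!is.finite(f)) || any(f < 0)) stop("oscillator strengths must be >= 0")
  grid <- seq(grid_from, grid_to, by = grid_by)
  if (any(E < grid_from | E > grid_to))
    warning(sum(E < grid_from | E > grid_to),
            " line(s) outside the grid; their tails are truncated")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  # column-wise accumulation keeps memory bounded for large ensembles
  intensity <- numeric(length(grid))
  block <- 500L
  for (start in seq(1L, length(E), by = block)) {
    idx <- start:min(start + block - 1L, length(E))
    d <- outer(grid, E[idx], "-")
    intensity <- intensity +
      as.vector(exp(-d^2 / (2 * sigma^2)) %*% f[idx])
  }
  intensity <- intensity / (length(E) * sigma * sqrt(2 * pi))
  structure(
    list(energy_eV = grid, intensity = intensity, n_records = length(E),
         broadening_fwhm = fwhm, shift_eV = 0),
    class = "ensemble_spectrum"
  )
}

#' @export
print.ensemble_spectrum <- function(x, ...) {
  cat(sprintf(
    "ensemble spectrum: %d lines, grid %.3g-%.3g eV (%d pts), fwhm %.3g eV, shift %+.4g eV\n",
    x$n_records, min(x$energy_eV), max(x$energy_eV), length(x$energy_eV),
    x$broadening_fwhm, x$shift_eV))
  invisible(x)
}

#' Integrated intensity of an ensemble spectrum
#'
#' Trapezoidal integral over the energy grid; equals the mean oscillator
#' strength when all lines lie well inside the grid.
#'
#' @param spec an `ensemble_spectrum`
#' @export
spectrum_integral <- function(spec) {
  x <- spec$energy_eV; y <- spec$intensity
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Convert an energy-domain spectrum to the wavelength domain
#'
#' lambda = hc/E with hc = 1239.842 eV nm. By default the intensity is
#' carried over unchanged (the common convention for plotting ensemble
#' spectra); `jacobian = TRUE` multiplies by E^2/hc so that intensity
#' per unit wavelength is conserved.
#'
#' @param spec an `ensemble_spectrum`
#' @param jacobian apply the E^2/hc density correction (default FALSE)
#' @return data.frame `wavelength_nm`, `intensity`, sorted by increasing
#'   wavelength
#' @export
to_wavelength <- function(spec, jacobian = FALSE) {
  hc <- azo_constants$hc_eV_nm
  E <- spec$energy_eV + spec$shift_eV
  lam <- hc / E
  inten <- if (jacobian) spec$intensity * E^2 / hc else spec$intensity
  ord <- order(lam)
  data.frame(wavelength_nm = lam[ord], intensity = inten[ord])
}

#' Experimental UV-vis spectrum with Beer-Lambert metadata
#'
#' @param wavelength_nm increasing wavelength grid, nm
#' @param absorbance absorbance, AU
#' @param concentration_M molar concentration, mol/L
#' @param path_cm optical path length, cm
#' @export
experimental_spectrum <- function(wavelength_nm, absorbance,
                                  concentration_M = NA_real_,
                                  path_cm = NA_real_) {
  if (length(wavelength_nm) != length(absorbance))
    stop("wavelength and absorbance lengths differ")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  structure(
    list(wavelength_nm = wavelength_nm, absorbance = absorbance,
         concentration_M = concentration_M, path_cm = path_cm),
    class = "experimental_spectrum"
  )
}

#' Molar absorptivity from an experimental spectrum
#'
#' Beer-Lambert: epsilon(lambda) = A(lambda) / (c * l).
#'
#' @param spec an [experimental_spectrum()] with concentration and path
#'   metadata
#' @param unit `"L_mol_cm"` (default) or `"L_mmol_cm"` (values divided
#'   by 1000)
#' @return data.frame `wavelength_nm`, `epsilon`
#' @export
epsilon_from_absorbance <- function(spec, unit = c("L_mol_cm", "L_mmol_cm")) {
  unit <- match.arg(unit)
  c_M <- spec$concentration_M; l <- spec$path_cm
  if (!is.finite(c_M) || c_M <= 0 || !is.finite(l) || l <= 0)
    stop("concentration and path length metadata required and > 0")
  eps <- spec$absorbance / (c_M * l)
  if (unit == "L_mmol_cm") eps <- eps / 1000
  data.frame(wavelength_nm = spec$wavelength_nm, epsilon = eps)
}

#' Calibrate a systematic energy shift against a measured spectrum
#'
#' Computed ensemble spectra carry a systematic offset of the excitation
#' energies; this finds the scalar shift (and a free amplitude scale,
#' since computed intensities are relative) that minimises the
#' least-squares difference to an experimental trace inside a
#' wavelength window. The shift is searched on a 1 meV grid over
#' `shift_range` with 3-point parabolic refinement; the scale is solved
#' in closed form at each candidate shift.
#'
#' @param computed an `ensemble_spectrum`
#' @param experimental an [experimental_spectrum()] (or data.frame with
#'   `wavelength_nm` and `absorbance`/`intensity`)
#' @param window wavelength window `c(lo, hi)` in nm (default 380-780)
#' @param shift_range search range in eV (default `c(-0.5, 0.5)`)
#' @param peak_normalize compare peak-normalised traces (drops the free
#'   scale; default FALSE)
#' @return list: `shift_eV`, `scale`, `rss`, `shifted` (the computed
#'   spectrum with `shift_eV` recorded)
#' @export
calibrate_shift <- function(computed, experimental, window = c(380, 780),
                            shift_range = c(-0.5, 0.5),
                            peak_normalize = FALSE) {
  exp_w <- experimental$wavelength_nm
  exp_a <- if (!is.null(experimental$absorbance)) experimental$absorbance
           else experimental$intensity
  sel <- exp_w >= window[1] & exp_w <= window[2]
  hc <- azo_constants$hc_eV_nm
  grid_E <- computed$energy_eV
  comp_rng <- hc / rev(range(grid_E))   # nm range covered by the grid
  if (!any(sel) ||
      max(exp_w[sel]) < comp_rng[1] || min(exp_w[sel]) > comp_rng[2])
    stop("window does not overlap both spectra")
  wl <- exp_w[sel]; target <- exp_a[sel]
  if (peak_normalize && max(target) > 0) target <- target / max(target)
  E_eval <- hc / wl
  rss_of <- function(shift) {
    # intensity at shifted energies: I((E - shift)) on the original grid
    yi <- approx(grid_E, computed$intensity, xout = E_eval - shift,
                 yleft = 0, yright = 0)$y
    if (peak_normalize) {
      if (max(yi) <= 0) return(list(rss = sum(target^2), scale = 1))
      yi <- yi / max(yi)
      return(list(rss = sum((target - yi)^2), scale = 1))
    }
    s <- if (sum(yi^2) > 0) sum(yi * target) / sum(yi^2) else 0
    list(rss = sum((target - s * yi)^2), scale = s)
  }
  shifts <- seq(shift_range[1], shift_range[2], by = 0.001)
  rss <- vapply(shifts, function(s) rss_of(s)$rss, 0)
  i <- which.min(rss)
  best <- shifts[i]
  if (i > 1L && i < length(shifts)) {
    denom <- rss[i - 1] - 2 * rss[i] + rss[i + 1]
    if (denom > 0)
      best <- shifts[i] + 0.001 * (rss[i - 1] - rss[i + 1]) / (2 * denom)
  }
  fit <- rss_of(best)
  shifted <- computed
  shifted$shift_eV <- computed$shift_eV + best
  list(shift_eV = best, scale = fit$scale, rss = fit$rss, shifted = shifted)
}

#' Band maximum and tail extent of an absorption trace
#'
#' Locates the band maximum inside a wavelength window (argmax with
#' 3-point parabolic refinement) and the band-tail extent: the longest
#' wavelength in the window at which the intensity still reaches
#' `threshold_fraction` of the peak (linear interpolation between grid
#' points). The tail extent approximates the longest wavelength at
#' which absorption, and hence productive photoswitching, persists.
#'
#' @param trace data.frame with `wavelength_nm` and `intensity` (or
#'   `absorbance`), e.g. from [to_wavelength()]
#' @param window wavelength window `c(lo, hi)` in nm (default 380-780,
#'   the visible n->pi* region)
#' @param threshold_fraction tail threshold as a fraction of the peak
#'   (default 0.01)
#' @return list: `lambda_max_nm`, `intensity_max`, `tail_extent_nm`,
#'   `threshold_fraction`
#' @export
band_metrics <- function(trace, window = c(380, 780),
                         threshold_fraction = 0.01) {
  w <- trace$wavelength_nm
  y <- if (!is.null(trace$intensity)) trace$intensity else trace$absorbance
  sel <- which(w >= window[1] & w <= window[2])
  if (length(sel) < 3L) stop("window contains fewer than 3 points")
  w <- w[sel]; y <- y[sel]
  ord <- order(w); w <- w[ord]; y <- y[ord]
  if (diff(range(y)) <= 0) stop("flat trace: no band maximum in window")
  i <- which.max(y)
  lam_max <- w[i]; y_max <- y[i]
  if (i > 1L && i < length(y)) {
    d <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (d < 0) {
      frac <- (y[i - 1] - y[i + 1]) / (2 * d)
      lam_max <- w[i] + frac * (w[i + 1] - w[i])
      y_max <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * frac
    }
  }
  thr <- threshold_fraction * y_max
  above <- which(y >= thr)
  j <- max(above)
  tail_nm <- w[j]
  if (j < length(y) && y[j] > thr) {
    tail_nm <- w[j] + (w[j + 1] - w[j]) * (y[j] - thr) / (y[j] - y[j + 1])
  }
  tail_nm <- max(tail_nm, lam_max)
  list(lambda_max_nm = lam_max, intensity_max = y_max,
       tail_extent_nm = tail_nm, threshold_fraction = threshold_fraction)
}

#' Separation of the cis and trans band maxima
#'
#' lambda_max(trans) - lambda_max(cis), sign preserved. Ortho-substituted
#' azobenzenes show a characteristic ~50 nm split of the n->pi* maxima,
#' which is what enables selective visible-light addressing of the two
#' isomers.
#'
#' @param metrics_cis,metrics_trans [band_metrics()] results for the two
#'   isomers of the same compound
#' @return difference in nm
#' @export
cis_trans_split <- function(metrics_cis, metrics_trans) {
  metrics_trans$lambda_max_nm - metrics_cis$lambda_max_nm
}
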