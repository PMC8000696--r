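# Classical single-wavelength analyses: Stern-Volmer (SV), its
# double-logarithm form (DLSV, a linearised Hill equation), static-quenching
# classification, and interference-driven wavelength selection.

#' Single-wavelength quenching series
#'
#' The raw material of the SV and DLSV fits: the protein fluorescence at one
#' wavelength, without quencher (`f0`) and after each drug addition.
#'
#' @param f0 intensity without quencher (> 0).
#' @param q total quencher concentrations, mol/L, strictly increasing.
#' @param f intensities at each `q` (> 0).
#' @param wavelength monitored wavelength (nm), informational.
#' @param mode acquisition mode label, informational.
#' @return an object of class `quenching_series`.
#' @export
quenching_series <- function(f0, q, f, wavelength = NA_real_, mode = NA_character_) {
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be > 0")
  if (length(q) != length(f)) stop("q and f must have equal length")
  if (any(diff(q) <= 0)) stop("quencher concentrations must be strictly increasing")
  if (any(q <= 0)) stop("quencher concentrations must be > 0")
  if (any(!is.finite(f)) || any(f <= 0)) stop("all intensities must be > 0")
  structure(list(f0 = f0, q = as.numeric(q), f = as.numeric(f),
                 wavelength = wavelength, mode = mode),
            class = "quenching_series")
}

#' Stern-Volmer fit
#'
#' Fits `(F0 - F)/F = Kq * tau * [Q]` by least squares through the origin
#' (the SV equation has no intercept).  `KSV = Kq * tau` is the slope; the
#' bimolecular quenching constant `Kq` follows from the assumed unquenched
#' fluorophore lifetime `tau`.
#'
#' @param series a [quenching_series()].
#' @param tau average fluorophore lifetime without quencher, seconds.
#'   Tryptophan lifetimes in proteins fall in 2-7 ns; a value outside that
#'   range triggers a warning.  Default 5 ns (mid-range).
#' @return `sv_fit_result`: `ksv` (M^-1), `kq` (M^-1 s^-1), `tau`, `r2`.
#' @export
sv_fit <- function(series, tau = 5e-9) {
  stopifnot(inherits(series, "quenching_series"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be a positive time in seconds")
  if (tau < 2e-9 || tau > 7e-9)
    warning("tau outside the plausible 2-7 ns range for protein fluorophores")
  if (length(series$q) < 3) stop("need at least 3 titration points")
  y <- (series$f0 - series$f) / series$f
  x <- series$q
  ksv <- sum(x * y) / sum(x * x)
  fitted <- ksv * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum(y^2)                       # through-origin convention
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(ksv = ksv, kq = ksv / tau, tau = tau, r2 = r2,
                 n = length(x), wavelength = series$wavelength,
                 mode = series$mode),
            class = "sv_fit_result")
}

#' @export
print.sv_fit_result <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (through origin, n = %d)\n", x$n))
  cat(sprintf("  KSV = %.4g M^-1   tau = %.3g ns   Kq = %.4g M^-1 s^-1   R2 = %.4f\n",
              x$ksv, x$tau * 1e9, x$kq, x$r2))
  cat(sprintf("  mechanism: %s\n", classify_quenching(x)))
  invisible(x)
}

#' Classify the quenching mechanism from an SV fit
#'
#' An apparent bimolecular quenching constant above the diffusion limit in
#' water (~1e10 M^-1 s^-1) cannot arise from collisional quenching and
#' indicates ground-state (static) complex formation.
#'
#' @param result an `sv_fit_result`.
#' @param threshold diffusion-limited quenching constant, M^-1 s^-1.
#' @return `"static"` or `"dynamic-compatible"`.
#' @export
classify_quenching <- function(result, threshold = 1e10) {
  stopifnot(inherits(result, "sv_fit_result"))
  if (result$kq > threshold) "static" else "dynamic-compatible"
}

#' Double-logarithm Stern-Volmer (linearised Hill) fit
#'
#' Fits `log10((F0 - F)/F) = log10(Kb) + nH * log10([Q])` by unweighted
#' least squares with a free intercept (the intercept *is* the binding
#' constant).  The total quencher concentration stands in for the free one,
#' which is accurate only when the protein is in large deficit; with
#' comparable concentrations the recovered `log Kb` is biased, a known
#' restriction of the model.  Points with `F >= F0` carry no quenching
#' information on the log scale and are dropped with a warning.
#'
#' @param series a [quenching_series()].
#' @return `dlsv_fit_result`: `log_kb`, `nh`, standard errors, `r2`, number
#'   of points used.
#' @export
dlsv_fit <- function(series) {
  stopifnot(inherits(series, "quenching_series"))
  usable <- series$f < series$f0
  if (any(!usable))
    warning(sum(!usable), " point(s) with F >= F0 dropped from the DLSV fit")
  if (sum(usable) < 3)
    stop("fewer than 3 usable points (F < F0) for the DLSV fit")
  x <- log10(series$q[usable])
  y <- log10((series$f0 - series$f[usable]) / series$f[usable])
  fit <- stats::lm(y ~ x)
  # exact synthetic lines make summary.lm grumble about perfect fits
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  structure(list(log_kb = unname(cf[1, 1]), se_log_kb = unname(cf[1, 2]),
                 nh = unname(cf[2, 1]), se_nh = unname(cf[2, 2]),
                 r2 = sm$r.squared, n = sum(usable),
                 wavelength = series$wavelength, mode = series$mode),
            class = "dlsv_fit_result")
}

#' @export
print.dlsv_fit_result <- function(x, ...) {
  cat(sprintf("Double-logarithm Stern-Volmer fit (n = %d)\n", x$n))
  cat(sprintf("  log Kb = %s   nH = %s   R2 = %.4f\n",
              format_constant(x$log_kb, x$se_log_kb),
              format_constant(x$nh, x$se_nh), x$r2))
  invisible(x)
}

#' Drug interference over the protein signal
#'
#' The fraction of the total fluorescence at a wavelength that is due to the
#' drug itself, `100 * I_drug / I_total` (percent).  Single-wavelength
#' analyses are considered usable below 10 % interference.
#'
#' @param i_drug drug-only intensity.
#' @param i_total total intensity (`>= i_drug`, `> 0`).
#' @return interference, percent.
#' @export
interference_percent <- function(i_drug, i_total) {
  if (any(!is.finite(i_total)) || any(i_total <= 0)) stop("i_total must be > 0")
  if (any(i_drug < 0)) stop("i_drug must be >= 0")
  if (any(i_drug > i_total)) stop("i_drug cannot exceed i_total")
  100 * i_drug / i_total
}

#' Select the monitoring wavelength for single-wavelength fits
#'
#' Scans the grid for the wavelength with the maximum protein signal among
#' those where the drug interference (`100 * drug / (protein + drug)`) does
#' not exceed `threshold`.  When no wavelength qualifies the result carries
#' `wavelength = NA` and `usable = FALSE` (drugs with strong intrinsic
#' fluorescence across the whole range cannot be treated with the DLSV
#' approach at all).
#'
#' @param protein_spectrum,drug_spectrum [spectrum()] objects of the pure
#'   compounds on identical grids.
#' @param threshold maximum tolerable interference, percent.
#' @return list: `wavelength`, `usable`, `interference` (at the selection),
#'   and a `diagnostics` data.frame over the full grid.
#' @export
select_wavelength <- function(protein_spectrum, drug_spectrum, threshold = 10) {
  stopifnot(inherits(protein_spectrum, "spectrum"),
            inherits(drug_spectrum, "spectrum"))
  wp <- protein_spectrum$grid$wavelengths
  wd <- drug_spectrum$grid$wavelengths
  if (length(wp) != length(wd) || any(wp != wd))
    stop("protein and drug spectra must share an identical wavelength grid")
  p <- protein_spectrum$intensities
  d <- drug_spectrum$intensities
  tot <- p + d
  interf <- ifelse(tot > 0, 100 * d / tot, 0)
  eligible <- interf <= threshold
  diagnostics <- data.frame(wavelength = wp, protein = p, drug = d,
                            interference = interf, eligible = eligible)
  if (!any(eligible))
    return(list(wavelength = NA_real_, usable = FALSE,
                interference = NA_real_, diagnostics = diagnostics))
  best <- which(eligible)[which.max(p[eligible])]
  list(wavelength = wp[best], usable = TRUE, interference = interf[best],
       diagnostics = diagnostics)
}
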