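# Spectral model: a solution's fluorescence spectrum is the sum of the
# spectra of all fluorescent species, If_j = sum_i C_i * Phi_{i,j}, where
# Phi_{i,j} is the molar fluorescence of species i at wavelength j.

#' Wavelength grid of an acquisition mode
#'
#' Three modes are supported: conventional `emission` scans (excitation
#' 285 nm, emission 295-550 nm by default) and two synchronous scans with a
#' fixed excitation-emission offset (`sync15`: delta 15 nm, tyrosine
#' environment; `sync60`: delta 60 nm, tryptophan environment; both
#' 230-400 nm by default).
#'
#' @param mode one of `"emission"`, `"sync15"`, `"sync60"`.
#' @param wavelengths strictly increasing wavelengths (nm); default mode
#'   range at `step` nm spacing.
#' @param step grid step (nm) when `wavelengths` is NULL.
#' @param excitation excitation wavelength (nm), emission mode only.
#' @param delta synchronous offset (nm); defaults to the mode's value.
#' @return an object of class `wavelength_grid`.
#' @export
wavelength_grid <- function(mode = c("emission", "sync15", "sync60"),
                            wavelengths = NULL, step = 1,
                            excitation = 285, delta = NULL) {
  mode <- match.arg(mode)
  if (is.null(wavelengths)) {
    rng <- if (mode == "emission") c(295, 550) else c(230, 400)
    wavelengths <- seq(rng[1], rng[2], by = step)
  }
  if (length(wavelengths) < 1 || any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(delta)) delta <- switch(mode, emission = NA_real_,
                                      sync15 = 15, sync60 = 60)
  structure(list(mode = mode, wavelengths = as.numeric(wavelengths),
                 excitation = if (mode == "emission") excitation else NA_real_,
                 delta = delta),
            class = "wavelength_grid")
}

#' A single fluorescence spectrum
#'
#' @param grid a [wavelength_grid()].
#' @param intensities intensities (arbitrary, instrument-linear units), one
#'   per grid wavelength.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(grid, intensities) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(intensities) != length(grid$wavelengths))
    stop("intensities length does not match the wavelength grid")
  structure(list(grid = grid, intensities = as.numeric(intensities)),
            class = "spectrum")
}

#' Model spectrum of a solution from its speciation
#'
#' Additive species fluorescence: `If_j = sum_i C_i * Phi_{i,j}` over the
#' species present in `phi`.  Linear and homogeneous in every concentration.
#'
#' @param speciation a `speciation` object (one solution).
#' @param phi molar fluorescence matrix: rows = species (rownames required),
#'   columns = wavelengths of `grid`; units intensity per mol/L.
#' @param grid the [wavelength_grid()] the columns of `phi` live on.
#' @return a [spectrum()].
#' @export
compute_spectrum <- function(speciation, phi, grid) {
  stopifnot(inherits(speciation, "speciation"), is.matrix(phi))
  if (ncol(phi) != length(grid$wavelengths))
    stop("phi has ", ncol(phi), " columns but the grid has ",
         length(grid$wavelengths), " wavelengths")
  conc <- c(speciation$free, speciation$complexes)
  if (is.null(rownames(phi)) || !all(rownames(phi) %in% names(conc)))
    stop("phi rownames must be species names of the model")
  spectrum(grid, as.numeric(conc[rownames(phi)] %*% phi))
}

.phi_ols <- function(C, Y, nonneg = FALSE) {
  k <- ncol(C)
  dec <- qr(C)
  if (dec$rank < k) {
    dep <- colnames(C)[dec$pivot[seq.int(dec$rank + 1L, k)]]
    stop("molar fluorescences are not identifiable: species ",
         paste(dep, collapse = ", "),
         " have collinear concentration profiles")
  }
  if (!nonneg) {
    phi <- qr.coef(dec, Y)
  } else {
    # small k: exact non-negative LS by best feasible subset, vectorised
    # across wavelengths
    if (k > 12) stop("non-negative solve supports at most 12 species")
    nw <- ncol(Y)
    phi <- matrix(0, k, nw)
    best <- rep(Inf, nw)
    for (mask in seq_len(2^k) - 1L) {
      on <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      if (!any(on)) {
        rss <- colSums(Y^2)
        cand <- matrix(0, k, nw)
      } else {
        Cs <- C[, on, drop = FALSE]
        d <- qr(Cs)
        if (d$rank < sum(on)) next
        b <- qr.coef(d, Y)
        res <- Y - Cs %*% b
        rss <- colSums(res^2)
        ok <- colSums(b < -1e-12 * max(abs(b), 1)) == 0
        rss[!ok] <- Inf
        cand <- matrix(0, k, nw)
        cand[on, ] <- b
      }
      upd <- rss < best
      if (any(upd)) {
        phi[, upd] <- cand[, upd, drop = FALSE]
        best[upd] <- rss[upd]
      }
    }
  }
  rownames(phi) <- colnames(C)
  phi
}

#' Estimate molar fluorescences by linear least squares
#'
#' Given the species concentrations of a titration and the observed spectra,
#' recovers the per-species per-wavelength molar fluorescence matrix `Phi` as
#' the ordinary least-squares solution of `Y = C Phi`, wavelength by
#' wavelength (the concentrations form the design matrix).  This is the
#' linear half of the separable global fit; it is also available directly,
#' e.g. to extract the unitary spectrum of a complex after fitting.
#'
#' @param speciations a `speciation_series` (or a concentration matrix,
#'   solutions x species, with colnames).
#' @param observed list of [spectrum()] objects (or an intensity matrix,
#'   solutions x wavelengths).
#' @param model required when `speciations` is a series: the model, used to
#'   select fluorescent species.
#' @param nonneg constrain `Phi >= 0` (exact small-subset solver).  Off by
#'   default: the least-squares problem is unconstrained, and small negative
#'   values are a diagnostic worth seeing (a warning is raised).
#' @return list with `phi` (species x wavelengths), `residuals`
#'   (solutions x wavelengths) and `rss_per_wavelength`.
#' @export
estimate_molar_fluorescence <- function(speciations, observed, model = NULL,
                                        nonneg = FALSE) {
  if (inherits(speciations, "speciation_series")) {
    if (is.null(model)) stop("model is required with a speciation_series")
    C <- species_concentrations(speciations, model, fluorescent_only = TRUE)
  } else {
    C <- as.matrix(speciations)
    if (is.null(colnames(C))) stop("concentration matrix must have species colnames")
  }
  Y <- if (is.matrix(observed)) observed else
    t(vapply(observed, function(s) s$intensities, numeric(length(observed[[1]]$intensities))))
  if (nrow(Y) != nrow(C))
    stop("number of spectra (", nrow(Y), ") does not match number of solutions (",
         nrow(C), ")")
  if (nrow(C) < ncol(C))
    stop("need at least as many solutions as fluorescent species")
  phi <- .phi_ols(C, Y, nonneg = nonneg)
  if (!nonneg && any(phi < -1e-8 * max(abs(phi), 1e-300))) {
    bad <- rownames(phi)[apply(phi < -1e-8 * max(abs(phi), 1e-300), 1, any)]
    warning("negative molar fluorescence estimated for species: ",
            paste(bad, collapse = ", "))
  }
  res <- Y - C %*% phi
  list(phi = phi, residuals = res, rss_per_wavelength = colSums(res^2))
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local polynomial least-squares filter; reproduces any polynomial of
#' degree `<= polyorder` exactly.  Edge points are smoothed with the
#' polynomial fitted to the first/last window.  Off by default everywhere in
#' the package: smoothing is the instrument's job and is offered only for raw
#' exported traces.
#'
#' @param spec a [spectrum()].
#' @param window odd window length (points), `>= 3`.
#' @param polyorder polynomial order, `< window`.
#' @return the smoothed [spectrum()] on the same grid.
#' @export
smooth_spectrum <- function(spec, window = 11L, polyorder = 3L) {
  stopifnot(inherits(spec, "spectrum"))
  n <- length(spec$intensities)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (polyorder < 0L || polyorder >= window)
    stop("polyorder must satisfy 0 <= polyorder < window")
  if (window > n) stop("window exceeds spectrum length")
  h <- (window - 1L) %/% 2L
  X <- outer(seq(-h, h), 0:polyorder, `^`)
  hat <- X %*% solve(crossprod(X), t(X))   # smoothing (projection) matrix
  y <- spec$intensities
  out <- y
  mid <- hat[h + 1L, ]
  for (i in seq.int(h + 1L, n - h))
    out[i] <- sum(mid * y[(i - h):(i + h)])
  out[1:h] <- (hat %*% y[1:window])[1:h]
  out[(n - h + 1L):n] <- (hat %*% y[(n - window + 1L):n])[(window - h + 1L):window]
  spectrum(spec$grid, out)
}
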