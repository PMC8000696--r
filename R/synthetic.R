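# Synthetic titration generator.  Emulates the cuvette protocol the analysis
# assumes: a fixed protein aliquot, sixteen consecutive additions of a
# concentrated drug stock covering a drug:protein ratio range, full dilution
# bookkeeping, species spectra built from smooth Gaussian bands, and seeded
# additive Gaussian noise.

#' Titration protocol
#'
#' Defaults mirror a typical serum-albumin quenching experiment: a 2700 uL
#' aliquot of 3-5 uM protein in the cuvette, sixteen consecutive additions
#' of a 1000 uM (or 300 uM for poorly soluble drugs) stock, covering a
#' drug:protein concentration ratio of 0.4-14.
#'
#' @param protein_uM initial protein concentration in the cuvette, uM.
#' @param stock_uM drug stock concentration, uM.
#' @param initial_volume_uL starting cuvette volume, uL.
#' @param n_additions number of drug additions (titration points beyond the
#'   drug-free one).
#' @param ratio_range target drug:protein total-concentration ratio at the
#'   first and last addition.
#' @param spacing ratio spacing across additions.
#' @param temperature degrees Celsius.
#' @param modes acquisition modes to simulate.
#' @param wavelength_step grid step, nm.
#' @param seed integer seed; mandatory, so a protocol pins down its dataset
#'   bit-for-bit (no global RNG state is consumed).
#' @return an object of class `titration_protocol`.
#' @export
titration_protocol <- function(protein_uM = 4.5, stock_uM = 1000,
                               initial_volume_uL = 2700, n_additions = 16L,
                               ratio_range = c(0.4, 14),
                               spacing = c("geometric", "linear"),
                               temperature = 20,
                               modes = c("emission", "sync15", "sync60"),
                               wavelength_step = 1, seed) {
  spacing <- match.arg(spacing)
  if (missing(seed)) stop("a seed is mandatory in a titration protocol")
  if (n_additions < 1) stop("n_additions must be >= 1")
  if (protein_uM <= 0 || stock_uM <= 0 || initial_volume_uL <= 0)
    stop("concentrations and volumes must be positive")
  if (length(ratio_range) != 2 || diff(ratio_range) <= 0 || ratio_range[1] <= 0)
    stop("ratio_range must be increasing and positive")
  modes <- match.arg(modes, c("emission", "sync15", "sync60"), several.ok = TRUE)
  structure(list(protein_uM = protein_uM, stock_uM = stock_uM,
                 initial_volume_uL = initial_volume_uL,
                 n_additions = as.integer(n_additions),
                 ratio_range = ratio_range, spacing = spacing,
                 temperature = temperature, modes = modes,
                 wavelength_step = wavelength_step, seed = as.integer(seed)),
            class = "titration_protocol")
}

#' Plan the titration additions with dilution bookkeeping
#'
#' Computes the stock volume to add at every step so that the total
#' drug:protein concentration ratio follows the protocol's spacing, and
#' tracks the dilution of both components.  Because both totals share the
#' cuvette volume, the ratio after the k-th addition depends only on the
#' cumulative added volume `W_k = ratio_k * V0 * [P]0 / [stock]`, which makes
#' the plan exact.  Protocols whose final ratio would require growing the
#' cuvette volume by more than 20 % are rejected (the protein would be
#' diluted out of the calibrated linear range): use a more concentrated
#' stock.
#'
#' @param protocol a [titration_protocol()].
#' @return data.frame: `solution_id`, `added_uL` (this step),
#'   `volume_uL` (cumulative), `total_s_um`, `total_q_um` (uM, dilution
#'   corrected), `ratio`, `temperature`.  Row 1 is the drug-free point.
#' @export
plan_additions <- function(protocol) {
  stopifnot(inherits(protocol, "titration_protocol"))
  p <- protocol
  ratios <- if (p$spacing == "geometric") {
    p$ratio_range[1] * (p$ratio_range[2] / p$ratio_range[1])^
      ((seq_len(p$n_additions) - 1) / max(p$n_additions - 1, 1))
  } else {
    seq(p$ratio_range[1], p$ratio_range[2], length.out = p$n_additions)
  }
  if (p$n_additions == 1) ratios <- p$ratio_range[2]
  n_prot <- p$initial_volume_uL * p$protein_uM        # nmol, conserved
  W <- ratios * n_prot / (p$stock_uM)                 # cumulative added uL
  if (max(W) > 0.2 * p$initial_volume_uL)
    stop(sprintf(
      "protocol error: reaching ratio %.3g needs %.0f uL of stock (> 20%% of the %g uL aliquot); use a stock above %.0f uM",
      max(ratios), max(W), p$initial_volume_uL,
      max(ratios) * p$protein_uM / 0.2))
  W <- c(0, W)
  vol <- p$initial_volume_uL + W
  data.frame(
    solution_id = sprintf("sol%02d", seq_along(W)),
    added_uL = c(0, diff(W)),
    volume_uL = vol,
    total_s_um = n_prot / vol,
    total_q_um = p$stock_uM * W / vol,
    ratio = c(0, ratios),
    temperature = p$temperature)
}

gaussian_bands <- function(wavelengths, peaks) {
  if (is.null(peaks) || !nrow(peaks)) return(numeric(length(wavelengths)))
  out <- numeric(length(wavelengths))
  for (i in seq_len(nrow(peaks)))
    out <- out + peaks$amplitude[i] *
      exp(-(wavelengths - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  out
}

#' Ground truth for a simulated titration
#'
#' Pairs a binding model (the true constants) with per-mode species spectra
#' given as sums of Gaussian bands, plus the noise level.
#'
#' @param model an [equilibrium_model()] holding the generating constants.
#' @param peaks nested named list: `peaks[[mode]][[species]]` is a data.frame
#'   with columns `center` (nm), `width` (nm, Gaussian sd) and `amplitude`
#'   (intensity per uM of the species).  Species without an entry in a mode
#'   do not emit there.
#' @param noise_sd_fraction additive Gaussian noise, as a fraction of the
#'   maximum clean intensity of each mode.  Default 0.5 %.
#' @param sync60_high_intensity flag marking drugs whose delta-60 synchronous
#'   spectra are so intense that they should be down-weighted (or excluded)
#'   in a joint fit.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(model, peaks, noise_sd_fraction = 0.005,
                         sync60_high_intensity = FALSE) {
  stopifnot(inherits(model, "equilibrium_model"))
  fl <- model$species$name[model$species$fluorescent]
  for (md in names(peaks)) {
    unknown <- setdiff(names(peaks[[md]]), model$species$name)
    if (length(unknown))
      stop("peaks reference unknown species: ", paste(unknown, collapse = ", "))
    dark <- setdiff(names(peaks[[md]]), fl)
    if (length(dark))
      stop("peaks given for non-fluorescent species: ",
           paste(dark, collapse = ", "))
  }
  structure(list(model = model, peaks = peaks,
                 noise_sd_fraction = noise_sd_fraction,
                 sync60_high_intensity = sync60_high_intensity),
            class = "ground_truth")
}

#' True molar fluorescence matrix of a ground truth on a grid
#'
#' @param truth a [ground_truth()].
#' @param grid a [wavelength_grid()].
#' @return matrix (fluorescent species x wavelengths), intensity per mol/L.
#' @export
phi_from_truth <- function(truth, grid) {
  fl <- truth$model$species$name[truth$model$species$fluorescent]
  pk <- truth$peaks[[grid$mode]]
  phi <- t(vapply(fl, function(nm)
    gaussian_bands(grid$wavelengths, pk[[nm]]) * 1e6,   # per uM -> per mol/L
    numeric(length(grid$wavelengths))))
  rownames(phi) <- fl
  phi
}

#' Simulate a multiwavelength quenching titration
#'
#' Plans the additions, solves the speciation at every point, builds the
#' clean spectra of every mode from the ground-truth molar fluorescences,
#' and adds i.i.d. Gaussian noise with sd equal to
#' `noise_sd_fraction * max(clean intensity)` per mode.  Fully reproducible:
#' the same protocol seed yields a bit-identical dataset, and the global RNG
#' stream is left untouched.
#'
#' @param protocol a [titration_protocol()].
#' @param truth a [ground_truth()].
#' @param keep_clean store the noise-free intensity matrices in
#'   `dataset$clean`.
#' @return a `titration_dataset` (see [read_titration()] for the structure).
#' @export
simulate_titration <- function(protocol, truth, keep_clean = FALSE) {
  stopifnot(inherits(protocol, "titration_protocol"),
            inherits(truth, "ground_truth"))
  plan <- plan_additions(protocol)
  comp <- data.frame(total_s = plan$total_s_um * 1e-6,
                     total_q = plan$total_q_um * 1e-6)
  ser <- speciation_series(truth$model, comp)
  C <- species_concentrations(ser, truth$model, fluorescent_only = TRUE)
  grids <- lapply(stats::setNames(protocol$modes, protocol$modes),
                  function(md) wavelength_grid(md, step = protocol$wavelength_step))
  clean <- lapply(grids, function(g) {
    phi <- phi_from_truth(truth, g)
    Yc <- C %*% phi[colnames(C), , drop = FALSE]
    dimnames(Yc) <- list(plan$solution_id, g$wavelengths)
    Yc
  })
  spectra <- withr::with_seed(protocol$seed, lapply(clean, function(Yc) {
    sdev <- truth$noise_sd_fraction * max(Yc)
    if (sdev > 0) Yc + matrix(stats::rnorm(length(Yc), sd = sdev),
                              nrow(Yc), ncol(Yc)) else Yc
  }))
  structure(list(
    spectra = spectra, grids = grids,
    compositions = data.frame(
      solution_id = plan$solution_id,
      total_s_um = plan$total_s_um, total_q_um = plan$total_q_um,
      volume_uL = plan$volume_uL, temperature = plan$temperature),
    metadata = list(source = "quenchfit simulate",
                    protocol = unclass(protocol),
                    sync60_high_intensity = truth$sync60_high_intensity),
    clean = if (keep_clean) clean else NULL
  ), class = "titration_dataset")
}

# protein band positions: emission maximum near 346 nm, synchronous maxima
# near 285-286 nm
.protein_peaks <- function() list(
  emission = data.frame(center = 346, width = 25, amplitude = 1000),
  sync15   = data.frame(center = 286, width = 10, amplitude = 400),
  sync60   = data.frame(center = 286, width = 12, amplitude = 800))

# quenched complex band: scaled down, shifted and possibly narrowed -- the
# usual signature of a changed fluorophore microenvironment on binding
.attenuate <- function(peaks, f, shift = 0, wscale = 1)
  transform(peaks, amplitude = amplitude * f, center = center + shift,
            width = width * wscale)

#' Drug-like ground-truth presets
#'
#' Four synthetic archetypes of NSAID-albumin systems, with generating
#' constants at the requested temperature and spectral behaviour chosen to
#' reproduce each drug's qualitative interference pattern:
#'
#' * `naproxen`: one 1:1 site; the free drug fluoresces strongly in the
#'   emission and delta-60 synchronous modes, weakly at delta 15.
#' * `diflunisal`: two sites (1:1 and 1:2); minor drug interference.
#' * `flurbiprofen`: two sites with close constants; strong drug
#'   fluorescence in all modes and very intense delta-60 spectra (the
#'   `sync60_high_intensity` flag is set, motivating the staged fit).
#' * `ibuprofen`: binding occurs away from the fluorophores, so the complex
#'   spectrum equals the protein spectrum and the titration carries no
#'   quenching signal; fitting this preset is *expected* to fail to pin a
#'   constant (the generating constant here is a synthetic stand-in of the
#'   order seen by calorimetry, not a fluorescence-derived value).
#'
#' @param temperature 20, 25 or 37 (degrees Celsius).
#' @return named list; each element has `$truth` (a [ground_truth()]) and
#'   `$protein_uM`, `$stock_uM`, `$ratio_range` (protocol defaults for that
#'   drug; the poorly soluble flurbiprofen, titrated from a 300 uM stock
#'   into a 5 uM protein aliquot, only reaches a 12-fold excess within the
#'   20% volume budget).
#' @export
drug_presets <- function(temperature = 20) {
  tkey <- as.character(temperature)
  constants <- list(
    naproxen     = list("20" = 4.88, "25" = 4.80, "37" = 4.66),
    diflunisal   = list("20" = c(5.74, 4.57), "25" = c(5.86, 4.70),
                        "37" = c(5.62, 4.49)),
    flurbiprofen = list("20" = c(4.91, 5.53), "25" = c(4.96, 5.52),
                        "37" = c(4.98, 5.22)),
    ibuprofen    = list("20" = 4.9, "25" = 4.9, "37" = 4.9))
  if (!tkey %in% names(constants$naproxen))
    stop("temperature must be one of 20, 25, 37")
  pp <- .protein_peaks()
  modes <- names(pp)

  species_peaks <- function(complex_att, drug_bands) {
    # per-mode list: protein, complexes (attenuated, slightly shifted protein
    # bands), free drug
    out <- lapply(stats::setNames(modes, modes), function(md) {
      l <- list(S = pp[[md]])
      for (nm in names(complex_att)) {
        ca <- complex_att[[nm]]
        l[[nm]] <- .attenuate(pp[[md]], ca[["att"]], ca[["shift"]],
                              if ("wscale" %in% names(ca)) ca[["wscale"]] else 1)
      }
      if (!is.null(drug_bands[[md]])) l$Q <- drug_bands[[md]]
      l
    })
    out
  }

  make <- function(log_k, complex_att, drug_bands, drug_fluor, sync60_hi = FALSE) {
    model <- equilibrium_model(log_k,
                               fluorescent_free = c(S = TRUE, Q = drug_fluor))
    ground_truth(model, species_peaks(complex_att, drug_bands),
                 sync60_high_intensity = sync60_hi)
  }

  list(
    naproxen = list(
      truth = make(constants$naproxen[[tkey]],
                   complex_att = list(SQ = c(att = 0.35, shift = -10)),
                   drug_bands = list(
                     emission = data.frame(center = 355, width = 28, amplitude = 150),
                     sync60   = data.frame(center = 300, width = 20, amplitude = 150)),
                   drug_fluor = TRUE),
      protein_uM = 3, stock_uM = 1000, ratio_range = c(0.4, 14)),
    diflunisal = list(
      truth = make(constants$diflunisal[[tkey]],
                   complex_att = list(
                     SQ = c(att = 0.6, shift = -12),
                     SQ2 = c(att = 0.05, shift = -30, wscale = 0.8)),
                   drug_bands = list(
                     emission = data.frame(center = 400, width = 30, amplitude = 25),
                     sync60   = data.frame(center = 310, width = 18, amplitude = 25)),
                   drug_fluor = TRUE),
      protein_uM = 4.5, stock_uM = 1000, ratio_range = c(0.4, 14)),
    flurbiprofen = list(
      truth = make(constants$flurbiprofen[[tkey]],
                   complex_att = list(
                     SQ = c(att = 0.6, shift = -12),
                     SQ2 = c(att = 0.05, shift = -30, wscale = 0.8)),
                   drug_bands = list(
                     emission = data.frame(center = 340, width = 30, amplitude = 60),
                     sync15   = data.frame(center = 290, width = 15, amplitude = 50),
                     sync60   = data.frame(center = 290, width = 18, amplitude = 400)),
                   drug_fluor = TRUE, sync60_hi = TRUE),
      protein_uM = 5, stock_uM = 300, ratio_range = c(0.4, 12)),
    ibuprofen = list(
      truth = make(constants$ibuprofen[[tkey]],
                   complex_att = list(SQ = c(att = 1.0, shift = 0)),   # complex emits like free protein
                   drug_bands = list(
                     emission = data.frame(center = 330, width = 25, amplitude = 60),
                     sync15   = data.frame(center = 288, width = 12, amplitude = 15),
                     sync60   = data.frame(center = 288, width = 14, amplitude = 60)),
                   drug_fluor = TRUE),
      protein_uM = 3, stock_uM = 1000, ratio_range = c(0.4, 14))
  )
}

#' Titration protocol matching a drug preset
#'
#' @param preset one element of [drug_presets()].
#' @param seed integer seed.
#' @param temperature degrees Celsius (should match the preset's constants).
#' @param ... further arguments to [titration_protocol()].
#' @return a [titration_protocol()].
#' @export
preset_protocol <- function(preset, seed, temperature = 20, ...) {
  titration_protocol(protein_uM = preset$protein_uM,
                     stock_uM = preset$stock_uM,
                     ratio_range = preset$ratio_range,
                     temperature = temperature, seed = seed, ...)
}
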