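# Dataset container and on-disk dialect.  Spectra travel as a long-format
# CSV (`solution_id,mode,wavelength_nm,intensity`); compositions and mode
# settings live in a `meta.json` sidecar.  Concentrations are micromolar in
# files and in the dataset container; conversion to mol/L happens once, at
# the solver boundary (dataset_compositions_molar()).

#' Assemble a titration dataset
#'
#' @param spectra named list per mode of intensity matrices
#'   (solutions x wavelengths).
#' @param grids named list per mode of [wavelength_grid()] objects.
#' @param compositions data.frame with `solution_id`, `total_s_um`,
#'   `total_q_um` (uM), `volume_uL`, `temperature`.
#' @param metadata free-form list.
#' @return an object of class `titration_dataset`.
#' @export
titration_dataset <- function(spectra, grids, compositions, metadata = list()) {
  stopifnot(is.list(spectra), is.list(grids),
            setequal(names(spectra), names(grids)))
  ns <- nrow(compositions)
  for (md in names(spectra)) {
    if (nrow(spectra[[md]]) != ns)
      stop("mode ", md, ": ", nrow(spectra[[md]]), " spectra for ", ns,
           " solutions")
    if (ncol(spectra[[md]]) != length(grids[[md]]$wavelengths))
      stop("mode ", md, ": intensity columns do not match the grid")
  }
  req <- c("solution_id", "total_s_um", "total_q_um")
  if (!all(req %in% names(compositions)))
    stop("compositions must contain ", paste(req, collapse = ", "))
  structure(list(spectra = spectra, grids = grids,
                 compositions = compositions, metadata = metadata),
            class = "titration_dataset")
}

# totals in mol/L for the solvers
dataset_compositions_molar <- function(data) {
  data.frame(total_s = data$compositions$total_s_um * 1e-6,
             total_q = data$compositions$total_q_um * 1e-6)
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat(sprintf("Titration dataset: %d solutions, modes: %s\n",
              nrow(x$compositions),
              paste(sprintf("%s (%d wl)", names(x$spectra),
                            vapply(x$spectra, ncol, 0L)), collapse = ", ")))
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a titration dataset
#'
#' `write_titration()` writes `spectra.csv` (long format:
#' `solution_id,mode,wavelength_nm,intensity`) and `meta.json` (per-solution
#' totals in uM, volumes, temperature; per-mode excitation / synchronous
#' offset) into a directory.  Numbers are written with 17 significant
#' digits, so `read_titration(write_titration(d))` reproduces every numeric
#' payload bit for bit.
#'
#' @param dataset a `titration_dataset`.
#' @param dir directory (created if absent).
#' @return `write_titration()` returns `dir` invisibly; `read_titration()`
#'   a `titration_dataset`.
#' @export
write_titration <- function(dataset, dir) {
  stopifnot(inherits(dataset, "titration_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(names(dataset$spectra), function(md) {
    Y <- dataset$spectra[[md]]
    wl <- dataset$grids[[md]]$wavelengths
    data.frame(solution_id = rep(dataset$compositions$solution_id,
                                 each = length(wl)),
               mode = md,
               wavelength_nm = fmt17(rep(wl, times = nrow(Y))),
               intensity = fmt17(as.vector(t(Y))))
  }))
  utils::write.csv(rows, file.path(dir, "spectra.csv"), row.names = FALSE,
                   quote = FALSE)
  comp <- dataset$compositions
  meta <- list(
    schema_version = "1.0",
    solutions = lapply(seq_len(nrow(comp)), function(i) list(
      id = comp$solution_id[i],
      # decimal strings with 17 significant digits: exact float round-trip,
      # which jsonlite's number serialisation does not guarantee
      total_S_uM = fmt17(comp$total_s_um[i]),
      total_Q_uM = fmt17(comp$total_q_um[i]),
      volume_uL = if ("volume_uL" %in% names(comp)) fmt17(comp$volume_uL[i]) else NA,
      temperature_C = if ("temperature" %in% names(comp)) comp$temperature[i] else NA)),
    modes = lapply(dataset$grids, function(g)
      list(excitation_nm = g$excitation, delta_nm = g$delta)),
    metadata = dataset$metadata)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_titration
#' @param dir directory containing `spectra.csv` and `meta.json`.
#' @export
read_titration <- function(dir) {
  csv <- file.path(dir, "spectra.csv")
  mj <- file.path(dir, "meta.json")
  if (!file.exists(csv) || !file.exists(mj))
    stop("expected spectra.csv and meta.json under ", dir)
  raw <- utils::read.csv(csv, colClasses = c("character", "character",
                                             "numeric", "numeric"))
  need <- c("solution_id", "mode", "wavelength_nm", "intensity")
  if (!all(need %in% names(raw)))
    stop("spectra.csv must have columns ", paste(need, collapse = ", "))
  meta <- jsonlite::read_json(mj)
  ids <- vapply(meta$solutions, function(s) s$id, "")
  comp <- data.frame(
    solution_id = ids,
    total_s_um = vapply(meta$solutions, function(s) as.numeric(s$total_S_uM), 0),
    total_q_um = vapply(meta$solutions, function(s) as.numeric(s$total_Q_uM), 0),
    volume_uL = vapply(meta$solutions, function(s)
      if (is.null(s$volume_uL) || identical(s$volume_uL, "NA")) NA_real_
      else as.numeric(s$volume_uL), 0),
    temperature = vapply(meta$solutions, function(s)
      if (is.null(s$temperature_C)) NA_real_ else as.numeric(s$temperature_C), 0))
  extra <- setdiff(unique(raw$solution_id), ids)
  if (length(extra))
    stop("spectra.csv has solution ids absent from meta.json: ",
         paste(extra, collapse = ", "))
  spectra <- list(); grids <- list()
  for (md in unique(raw$mode)) {
    if (!md %in% c("emission", "sync15", "sync60"))
      stop("unknown mode in spectra.csv: ", md)
    sub <- raw[raw$mode == md, ]
    ref_wl <- sub$wavelength_nm[sub$solution_id == sub$solution_id[1]]
    if (any(diff(ref_wl) <= 0))
      stop("non-monotone wavelengths for solution ", sub$solution_id[1],
           " in mode ", md)
    Y <- matrix(NA_real_, nrow = length(ids), ncol = length(ref_wl),
                dimnames = list(ids, ref_wl))
    for (id in ids) {
      rows <- sub[sub$solution_id == id, ]
      if (nrow(rows) != length(ref_wl) ||
          any(rows$wavelength_nm != ref_wl))
        stop("schema error in mode ", md, ": solution ", id,
             " does not cover the common wavelength grid")
      Y[id, ] <- rows$intensity
    }
    gmeta <- meta$modes[[md]]
    grids[[md]] <- wavelength_grid(
      md, wavelengths = ref_wl,
      excitation = if (!is.null(gmeta$excitation_nm) &&
                       !is.na(suppressWarnings(as.numeric(gmeta$excitation_nm))))
        as.numeric(gmeta$excitation_nm) else 285,
      delta = if (!is.null(gmeta$delta_nm) &&
                  !is.na(suppressWarnings(as.numeric(gmeta$delta_nm))))
        as.numeric(gmeta$delta_nm) else NULL)
    spectra[[md]] <- Y
  }
  titration_dataset(spectra, grids, comp,
                    metadata = if (is.null(meta$metadata)) list() else meta$metadata)
}

#' Extract a single-wavelength quenching series from a dataset
#'
#' Pulls the intensity at (or nearest to) one wavelength in one mode for
#' every titration point.  The drug-free solution provides `F0`.
#'
#' @param dataset a `titration_dataset`.
#' @param mode acquisition mode.
#' @param wavelength monitored wavelength, nm.
#' @return a [quenching_series()].
#' @export
quenching_series_from_dataset <- function(dataset, mode, wavelength) {
  stopifnot(inherits(dataset, "titration_dataset"))
  if (!mode %in% names(dataset$spectra)) stop("dataset has no mode ", mode)
  wl <- dataset$grids[[mode]]$wavelengths
  j <- which.min(abs(wl - wavelength))
  q <- dataset$compositions$total_q_um * 1e-6
  f <- dataset$spectra[[mode]][, j]
  i0 <- which(q == 0)
  if (length(i0) < 1) stop("no drug-free solution in the dataset (F0)")
  quenching_series(f0 = mean(f[i0]), q = q[-i0], f = f[-i0],
                   wavelength = wl[j], mode = mode)
}

# "5.74 (0.01)" table style; the estimate is rounded to the decimals of the
# standard error (one significant figure)
format_constant <- function(est, se = NA_real_) {
  if (!is.finite(se) || se <= 0) return(sprintf("%.2f", est))
  se1 <- signif(se, 1)
  dec <- max(0L, -floor(log10(se1)))
  sprintf("%.*f (%.*f)", dec, est, dec, se1)
}

#' Render a fit result as text or JSON
#'
#' Text reports mirror the conventional table layout, constants with their
#' standard deviations in parentheses; non-converged fits carry an explicit
#' warning banner.  JSON reports are schema-versioned.
#'
#' @param result a `global_fit`, `dlsv_fit_result` or `sv_fit_result`.
#' @param format `"text"` or `"json"`.
#' @return a character scalar (the document).
#' @export
report <- function(result, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- if (inherits(result, "global_fit")) {
      list(schema_version = "1.0", type = "global_fit",
           log_k = as.list(result$log_k),
           se_log_k = as.list(result$se_log_k),
           refined = result$refined,
           U = result$U, sd_residual = result$sd_residual,
           ns = result$ns, nw = result$nw,
           iterations = result$iterations, converged = result$converged,
           modes = result$modes)
    } else if (inherits(result, "dlsv_fit_result")) {
      list(schema_version = "1.0", type = "dlsv_fit",
           log_kb = result$log_kb, se_log_kb = result$se_log_kb,
           nh = result$nh, se_nh = result$se_nh, r2 = result$r2,
           n = result$n, wavelength = result$wavelength, mode = result$mode)
    } else if (inherits(result, "sv_fit_result")) {
      list(schema_version = "1.0", type = "sv_fit",
           ksv = result$ksv, kq = result$kq, tau = result$tau, r2 = result$r2,
           classification = classify_quenching(result), n = result$n)
    } else stop("unsupported result type")
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, na = "null")))
  }
  lines <- utils::capture.output(print(result))
  paste(lines, collapse = "\n")
}
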