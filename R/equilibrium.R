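# Equilibrium binding models: a macromolecule S (serum albumin) and a ligand
# Q (the quencher drug) forming complexes SsQq with formation constants
# Kb = [SsQq] / ([S]^s [Q]^q).

#' Define a drug-protein equilibrium binding model
#'
#' Builds a two-component equilibrium model in which a macromolecule `S`
#' (typically serum albumin) and a ligand `Q` (the quencher drug) associate
#' into one or more complexes `SsQq`.  Each complex carries a base-10 log
#' formation constant.  Constants may be supplied either *stepwise*
#' (`K1 = [SQ]/([S][Q])`, `K2 = [SQ2]/([SQ][Q])`, the convention used when
#' binding constants of 1:1 and 1:2 processes are reported) or *cumulative*
#' (`beta_q = [SQq]/([S][Q]^q)`).  Internally the model stores cumulative
#' constants, which is the natural parameterisation for the mass-balance
#' solver; [stepwise_log_k()] converts back.
#'
#' The free components are represented as degenerate species `(s=1,q=0)` and
#' `(s=0,q=1)` with `log beta = 0`, so that total concentrations are plain
#' sums `total_S = sum(s_i * C_i)`, `total_Q = sum(q_i * C_i)` over all
#' species.
#'
#' @param complexes either a numeric vector of stepwise log K values for the
#'   ladder `SQ, SQ2, ...` (the common case), or a data.frame with columns
#'   `s`, `q`, `log_k` and optionally `fluorescent`.
#' @param constants how `log_k` is to be interpreted: `"stepwise"` (default)
#'   or `"cumulative"`.  Stepwise input requires a complete `S Q_q` ladder
#'   (`s = 1`, `q = 1..m`).
#' @param fluorescent_free named logical, whether the free macromolecule and
#'   free ligand fluoresce.  The protein always does; the drug only for some
#'   compounds and acquisition modes.
#' @return an object of class `equilibrium_model`.
#' @examples
#' # diflunisal-albumin: two sites, stepwise log K 5.74 and 4.57
#' m <- equilibrium_model(c(5.74, 4.57))
#' stepwise_log_k(m)
#' @export
equilibrium_model <- function(complexes = numeric(0),
                              constants = c("stepwise", "cumulative"),
                              fluorescent_free = c(S = TRUE, Q = FALSE)) {
  constants <- match.arg(constants)
  if (is.numeric(complexes) && !is.data.frame(complexes)) {
    complexes <- if (length(complexes)) {
      data.frame(s = 1L, q = seq_along(complexes),
                 log_k = as.numeric(complexes), fluorescent = TRUE)
    } else {
      data.frame(s = integer(0), q = integer(0), log_k = numeric(0),
                 fluorescent = logical(0))
    }
  }
  stopifnot(is.data.frame(complexes),
            all(c("s", "q", "log_k") %in% names(complexes)))
  if (is.null(complexes$fluorescent)) complexes$fluorescent <- TRUE
  s <- as.integer(complexes$s); q <- as.integer(complexes$q)
  if (any(s < 0) || any(q < 0) || any(s + q < 1))
    stop("complex stoichiometries must satisfy s >= 0, q >= 0, s + q >= 1")
  key <- paste(s, q)
  if (anyDuplicated(key))
    stop("duplicate (s, q) stoichiometry in complex list")
  if (any(key %in% c("1 0", "0 1")))
    stop("free components (1,0)/(0,1) are implicit; list complexes only")
  if (!all(c("S", "Q") %in% names(fluorescent_free)))
    stop("fluorescent_free must name both S and Q")

  log_beta <- as.numeric(complexes$log_k)
  if (constants == "stepwise" && nrow(complexes)) {
    if (!all(s == 1L) || !setequal(q, seq_len(nrow(complexes))))
      stop("stepwise constants require a complete S Q_q ladder (s = 1, q = 1..m); ",
           "supply constants = \"cumulative\" otherwise")
    ord <- order(q)
    log_beta[ord] <- cumsum(as.numeric(complexes$log_k)[ord])
  }

  cname <- function(s, q) {
    paste0(if (s > 0) paste0("S", if (s > 1) s else "") else "",
           if (q > 0) paste0("Q", if (q > 1) q else "") else "")
  }
  species <- rbind(
    data.frame(name = "S", s = 1L, q = 0L, log_beta = 0,
               fluorescent = unname(fluorescent_free["S"])),
    data.frame(name = "Q", s = 0L, q = 1L, log_beta = 0,
               fluorescent = unname(fluorescent_free["Q"])),
    data.frame(name = mapply(cname, s, q), s = s, q = q,
               log_beta = log_beta,
               fluorescent = as.logical(complexes$fluorescent))
  )
  rownames(species) <- NULL
  structure(list(
    components = data.frame(name = c("S", "Q"),
                            role = c("macromolecule", "ligand")),
    species = species
  ), class = "equilibrium_model")
}

#' @export
print.equilibrium_model <- function(x, ...) {
  cat("Equilibrium binding model: S (macromolecule) + Q (ligand)\n")
  cx <- complex_species(x)
  if (!nrow(cx)) {
    cat("  no complexes\n")
  } else {
    sw <- stepwise_log_k(x)
    for (i in seq_len(nrow(cx)))
      cat(sprintf("  %-4s (s=%d, q=%d)  log beta = %.4f  log K(stepwise) = %s%s\n",
                  cx$name[i], cx$s[i], cx$q[i], cx$log_beta[i],
                  if (is.na(sw[cx$name[i]])) "-" else sprintf("%.4f", sw[cx$name[i]]),
                  if (cx$fluorescent[i]) "" else "  [dark]"))
  }
  invisible(x)
}

#' Complex species of a model
#'
#' @param model an `equilibrium_model`.
#' @return data.frame of the complex species (free components excluded).
#' @export
complex_species <- function(model) {
  sp <- model$species
  sp[!((sp$s == 1 & sp$q == 0) | (sp$s == 0 & sp$q == 1)), , drop = FALSE]
}

#' @rdname complex_species
#' @export
complex_names <- function(model) complex_species(model)$name

#' Cumulative and stepwise formation constants
#'
#' `log_beta()` returns the cumulative log formation constants of the
#' complexes (referenced to free S and Q).  `stepwise_log_k()` converts the
#' `S Q_q` ladder to stepwise constants, `log K(1,q) = log beta(1,q) -
#' log beta(1,q-1)`, the convention in which 1:1 / 1:2 binding constants are
#' reported; complexes outside a ladder get `NA`.
#'
#' @param model an `equilibrium_model`.
#' @return named numeric vector over the complex species.
#' @export
log_beta <- function(model) {
  cx <- complex_species(model)
  stats::setNames(cx$log_beta, cx$name)
}

#' @rdname log_beta
#' @export
stepwise_log_k <- function(model) {
  cx <- complex_species(model)
  out <- stats::setNames(rep(NA_real_, nrow(cx)), cx$name)
  for (i in seq_len(nrow(cx))) {
    if (cx$s[i] == 1L) {
      if (cx$q[i] == 1L) {
        out[i] <- cx$log_beta[i]
      } else {
        prev <- which(cx$s == 1L & cx$q == cx$q[i] - 1L)
        if (length(prev) == 1L) out[i] <- cx$log_beta[i] - cx$log_beta[prev]
      }
    }
  }
  out
}

#' Replace formation constants in a model
#'
#' @param model an `equilibrium_model`.
#' @param values named numeric vector (names = complex names).
#' @param constants `"cumulative"` (default) or `"stepwise"`; stepwise values
#'   are converted ladder-wise before assignment and must cover the full
#'   ladder of every affected complex.
#' @return the updated model.
#' @export
set_log_beta <- function(model, values, constants = c("cumulative", "stepwise")) {
  constants <- match.arg(constants)
  if (is.null(names(values)) || !all(names(values) %in% model$species$name))
    stop("values must be named with complex species names")
  if (constants == "stepwise") {
    sw <- stepwise_log_k(model)
    if (any(is.na(sw[names(values)])))
      stop("stepwise assignment only supported on the S Q_q ladder")
    sw[names(values)] <- values
    cx <- complex_species(model)
    ladder <- cx[cx$s == 1L, , drop = FALSE]
    ladder <- ladder[order(ladder$q), , drop = FALSE]
    values <- stats::setNames(cumsum(sw[ladder$name]), ladder$name)
  }
  idx <- match(names(values), model$species$name)
  model$species$log_beta[idx] <- unname(values)
  model
}

#' Read or write a binding model as JSON
#'
#' The file holds `components` and `species` arrays; each species records
#' `s`, `q`, `log_kb` and `fluorescent`, with a top-level `constants` field
#' stating whether `log_kb` is stepwise or cumulative.
#'
#' @param path file path.
#' @param model an `equilibrium_model`.
#' @param constants convention used in the file when writing.
#' @return `read_model()` returns an `equilibrium_model`;
#'   `write_model()` returns `path` invisibly.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  constants <- if (is.null(j$constants)) "stepwise" else j$constants
  sp <- j$species
  keep <- !((sp$s == 1 & sp$q == 0) | (sp$s == 0 & sp$q == 1))
  ff <- c(S = TRUE, Q = FALSE)
  if (any(sp$s == 1 & sp$q == 0)) ff["S"] <- sp$fluorescent[sp$s == 1 & sp$q == 0]
  if (any(sp$s == 0 & sp$q == 1)) ff["Q"] <- sp$fluorescent[sp$s == 0 & sp$q == 1]
  cx <- data.frame(s = sp$s[keep], q = sp$q[keep], log_k = sp$log_kb[keep],
                   fluorescent = sp$fluorescent[keep])
  equilibrium_model(cx, constants = constants, fluorescent_free = ff)
}

#' @rdname read_model
#' @export
write_model <- function(model, path, constants = c("stepwise", "cumulative")) {
  constants <- match.arg(constants)
  sp <- model$species
  log_kb <- sp$log_beta
  if (constants == "stepwise") {
    sw <- stepwise_log_k(model)
    idx <- match(names(sw), sp$name)
    bad <- is.na(sw)
    if (any(bad)) stop("model has non-ladder complexes; write cumulative constants")
    log_kb[idx] <- unname(sw)
  }
  jsonlite::write_json(list(
    constants = constants,
    components = model$components,
    species = data.frame(s = sp$s, q = sp$q, log_kb = log_kb,
                         fluorescent = sp$fluorescent)
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
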