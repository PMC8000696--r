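# Global multiwavelength analysis: refine formation constants by Gauss-Newton
# minimisation of the sum of squared intensity residuals over all solutions,
# wavelengths and acquisition modes, with the molar fluorescences eliminated
# by linear least squares inside every iteration (separable structure).

#' Specify a global fit
#'
#' @param model an [equilibrium_model()] with at least one complex.
#' @param refine names of the complex species whose constants are refined;
#'   the rest stay fixed at the model's values.  Default: all complexes.
#' @param modes acquisition modes entering the objective.
#' @param phi optional supplied molar fluorescences: named list per mode of
#'   species x wavelength matrices.  When NULL (default) the fluorescences
#'   are re-estimated by linear least squares inside every iteration.
#' @param weights optional named per-mode weights on the residuals (useful
#'   when one mode's intensities dwarf the others); default 1 for every mode.
#' @param start optional named starting values for the refined constants,
#'   *stepwise* log K.  Default 4.0 for every refined constant (the typical
#'   order of magnitude of drug-albumin association).
#' @param max_iter maximum Gauss-Newton iterations per start.
#' @param tol_u convergence threshold on the relative decrease of the
#'   objective U.
#' @param fd_step finite-difference step (log10 units) for the Jacobian.
#' @param n_starts number of multi-starts (1 disables); starts beyond the
#'   first are displaced by `+/- start_spread` log units to guard against
#'   local minima.  All basins found are reported.
#' @param start_spread displacement of the extra starts, log units.
#' @return an object of class `fit_spec`.
#' @export
fit_spec <- function(model, refine = complex_names(model),
                     modes = c("emission", "sync15", "sync60"),
                     phi = NULL, weights = NULL, start = NULL,
                     max_iter = 200L, tol_u = 1e-8, fd_step = 1e-4,
                     n_starts = 3L, start_spread = 1) {
  stopifnot(inherits(model, "equilibrium_model"))
  if (length(modes) < 1) stop("modes_used must be non-empty")
  modes <- match.arg(modes, c("emission", "sync15", "sync60"),
                     several.ok = TRUE)
  cx <- complex_names(model)
  if (length(cx) < 1) stop("the model has no complex species to fit")
  if (length(refine) < 1 && is.null(phi))
    stop("nothing to do: no refined constants and no supplied phi")
  if (!all(refine %in% cx))
    stop("unknown refined species: ",
         paste(setdiff(refine, cx), collapse = ", "))
  if (!is.null(start) &&
      (is.null(names(start)) || !all(names(start) %in% refine)))
    stop("start must be named with refined species")
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(modes %in% names(weights)))
      stop("weights must be named with every used mode")
  }
  structure(list(model = model, refine = refine, modes = modes, phi = phi,
                 weights = weights, start = start, max_iter = as.integer(max_iter),
                 tol_u = tol_u, fd_step = fd_step, n_starts = as.integer(n_starts),
                 start_spread = start_spread),
            class = "fit_spec")
}

# residuals + ancillary quantities for one parameter vector (cumulative
# log beta of the refined species); Phi eliminated per mode unless supplied
.gf_eval <- function(theta, ctx) {
  m <- set_log_beta(ctx$model, theta)
  ser <- speciation_series(m, ctx$comp)
  C <- species_concentrations(ser, m, fluorescent_only = TRUE)
  r <- vector("list", length(ctx$modes))
  phi <- vector("list", length(ctx$modes))
  names(r) <- names(phi) <- ctx$modes
  for (md in ctx$modes) {
    Y <- ctx$Y[[md]]
    P <- if (!is.null(ctx$phi_supplied)) {
      ctx$phi_supplied[[md]][colnames(C), , drop = FALSE]
    } else {
      .phi_ols(C, Y)
    }
    phi[[md]] <- P
    r[[md]] <- sqrt(ctx$w[[md]]) * (Y - C %*% P)
  }
  rv <- unlist(r, use.names = FALSE)
  list(r = rv, U = sum(rv^2), phi = phi, residuals = r, speciation = ser)
}

# evaluation that tolerates speciation blow-ups at absurd trial constants
.gf_try_eval <- function(theta, ctx) {
  tryCatch(.gf_eval(theta, ctx), error = function(e) NULL)
}

.gf_gauss_newton <- function(theta0, ctx, max_iter, tol_u, fd_step) {
  theta <- theta0
  ev <- .gf_try_eval(theta, ctx)
  if (is.null(ev))
    return(list(theta = theta, ev = list(U = Inf, r = NULL, phi = NULL,
                                         residuals = NULL),
                iterations = 0L, converged = FALSE, u_trace = Inf))
  u_trace <- ev$U
  converged <- FALSE
  iter <- 0L
  p <- length(theta)
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- matrix(0, length(ev$r), p)
    for (j in seq_len(p)) {
      th <- theta; th[j] <- th[j] + fd_step
      J[, j] <- (.gf_eval(th, ctx)$r - ev$r) / fd_step
    }
    JtJ <- crossprod(J)
    if (!all(is.finite(JtJ)))
      stop("non-finite Jacobian in the Gauss-Newton refinement")
    # far from the optimum a constant can be locally inert (its complex does
    # not yet form) and JtJ near-singular; a small ridge keeps the step
    # defined without changing converged answers
    if (rcond(JtJ) < 1e-12)
      JtJ <- JtJ + 1e-8 * max(diag(JtJ), .Machine$double.xmin) * diag(p)
    delta <- solve(JtJ, crossprod(J, ev$r))[, 1]
    # ev$r = obs - calc, J = d r / d theta, so the descent step is -delta;
    # clamp to 2 log units per iteration to keep trial constants sane
    mx <- max(abs(delta))
    if (mx > 2) delta <- delta * (2 / mx)
    lam <- 1
    accepted <- FALSE
    for (h in 0:10) {
      th_new <- theta - lam * delta
      ev_new <- .gf_try_eval(th_new, ctx)
      if (!is.null(ev_new) && ev_new$U <= ev$U) { accepted <- TRUE; break }
      lam <- lam / 2
    }
    if (!accepted) break                      # cannot improve: local minimum
    du <- ev$U - ev_new$U
    theta <- th_new; ev <- ev_new
    u_trace <- c(u_trace, ev$U)
    if (du <= tol_u * max(ev$U, .Machine$double.xmin) ||
        max(abs(lam * delta)) < 1e-12) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, ev = ev, iterations = iter, converged = converged,
       u_trace = u_trace, J = NULL)
}

#' Refine binding constants by global Gauss-Newton fitting
#'
#' Minimises `U = sum_modes sum_solutions sum_wavelengths
#' (If_exp - If_calc)^2` over the refined log formation constants.  Each
#' evaluation solves the mass balances at every titration point, eliminates
#' the molar fluorescences by linear least squares (unless supplied), and the
#' constants are updated by a Gauss-Newton step on a finite-difference
#' Jacobian with step-halving, so accepted iterations never increase `U`.
#' Standard errors come from the residual variance and the diagonal of
#' `(J'J)^-1`.
#'
#' @param spec a [fit_spec()].
#' @param data a `titration_dataset` (see [simulate_titration()] /
#'   [read_titration()]).
#' @return an object of class `global_fit`: stepwise `log_k` with standard
#'   errors, cumulative `log_beta`, `U`, `sd_residual`
#'   (`sqrt(U / (ns*nw - n_par))`), `phi_hat`, residual spectra per mode,
#'   the accepted-U trace, iteration count, convergence flag and all
#'   multi-start basins.
#' @export
refine_constants <- function(spec, data) {
  stopifnot(inherits(spec, "fit_spec"), inherits(data, "titration_dataset"))
  missing_modes <- setdiff(spec$modes, names(data$spectra))
  if (length(missing_modes))
    stop("dataset lacks mode(s): ", paste(missing_modes, collapse = ", "))
  comp <- dataset_compositions_molar(data)
  if (all(comp$total_q == 0))
    stop("binding constants are not identifiable: no quencher was added ",
         "at any titration point")
  ratios <- unique(signif(comp$total_q / comp$total_s, 8))
  n_ref <- length(spec$refine)
  if (n_ref > 0 && length(ratios) < 2 * n_ref)
    warning("only ", length(ratios), " distinct quencher:protein ratios for ",
            n_ref, " refined constant(s); the fit may be poorly determined")

  w <- lapply(stats::setNames(spec$modes, spec$modes),
              function(md) if (is.null(spec$weights)) 1 else spec$weights[[md]])
  Y <- lapply(stats::setNames(spec$modes, spec$modes),
              function(md) data$spectra[[md]])
  ns <- nrow(comp)
  nw_tot <- sum(vapply(Y, ncol, 0L))
  if (ns > 300 || any(vapply(Y, ncol, 0L) > 500))
    warning("large problem (> 300 solutions or > 500 wavelengths per ",
            "spectrum); expect slow refinement")
  ctx <- list(model = spec$model, comp = comp, modes = spec$modes, Y = Y,
              w = w, phi_supplied = spec$phi)

  # starting values: stepwise -> cumulative through the current model
  sw <- stepwise_log_k(spec$model)
  start_sw <- stats::setNames(rep(4.0, n_ref), spec$refine)
  if (!is.null(spec$start)) start_sw[names(spec$start)] <- spec$start
  if (n_ref == 0) {
    ev <- .gf_eval(stats::setNames(numeric(0), character(0)), ctx)
    run <- list(theta = numeric(0), ev = ev, iterations = 0L,
                converged = TRUE, u_trace = ev$U)
    basins <- list()
  } else {
    sw_full <- sw
    sw_full[spec$refine] <- start_sw
    m0 <- set_log_beta(spec$model, sw_full[!is.na(sw_full)], "stepwise")
    theta0 <- log_beta(m0)[spec$refine]
    shifts <- c(0, -spec$start_spread, spec$start_spread)[seq_len(max(1L, spec$n_starts))]
    runs <- lapply(shifts, function(dlt)
      .gf_gauss_newton(theta0 + dlt, ctx, spec$max_iter, spec$tol_u, spec$fd_step))
    us <- vapply(runs, function(r) r$ev$U, 0)
    if (!any(is.finite(us)))
      stop("speciation failed at every starting point; check the model and totals")
    run <- runs[[which.min(us)]]
    basins <- lapply(runs, function(r)
      list(log_beta = r$theta, U = r$ev$U, converged = r$converged))
  }

  theta <- run$theta; ev <- run$ev
  model_hat <- if (n_ref) set_log_beta(spec$model, theta) else spec$model

  # uncertainty: sigma^2 = U / dof, covariance = sigma^2 (J'J)^-1 on the
  # cumulative parameters, transformed linearly to the stepwise scale.
  # dof subtracts both the refined constants and (when estimated) the
  # linear molar-fluorescence parameters.
  n_phi <- if (is.null(spec$phi))
    sum(vapply(ev$phi, function(p) length(p), 0L)) else 0L
  dof <- ns * nw_tot - n_ref - n_phi
  sd_residual <- sqrt(ev$U / max(dof, 1L))
  se_sw <- stats::setNames(rep(NA_real_, length(sw)), names(sw))
  if (n_ref > 0) {
    J <- matrix(0, length(ev$r), n_ref)
    for (j in seq_len(n_ref)) {
      th <- theta; th[j] <- th[j] + spec$fd_step
      J[, j] <- (.gf_eval(th, ctx)$r - ev$r) / spec$fd_step
    }
    JtJ <- crossprod(J)
    if (!all(is.finite(JtJ)) || rcond(JtJ) < 1e-14)
      stop(structure(
        class = c("quenchfit_identifiability_error", "error", "condition"),
        list(message = paste0(
          "binding constants are not identifiable from these data: the ",
          "residuals are insensitive to ",
          paste(spec$refine, collapse = ", "),
          " at the solution (singular normal equations)"),
          call = sys.call(-1))))
    cov_cum <- tryCatch((ev$U / max(dof, 1L)) * solve(JtJ),
                        error = function(e) matrix(NA_real_, n_ref, n_ref))
    A <- .stepwise_transform(model_hat, spec$refine)
    cov_sw <- A %*% cov_cum %*% t(A)
    se_sw[spec$refine] <- sqrt(pmax(diag(cov_sw), 0))
    if (any(is.finite(se_sw[spec$refine]) & se_sw[spec$refine] > 0.5))
      warning("large standard error (> 0.5 log units) on ",
              paste(spec$refine[se_sw[spec$refine] > 0.5], collapse = ", "),
              "; the constant is poorly determined by these data")
  }

  structure(list(
    model = model_hat,
    log_beta = log_beta(model_hat),
    log_k = stepwise_log_k(model_hat),
    refined = spec$refine,
    se_log_k = se_sw,
    U = ev$U, sd_residual = sd_residual,
    ns = ns, nw = nw_tot, n_parameters = n_ref, n_phi = n_phi, dof = dof,
    iterations = run$iterations, converged = run$converged,
    phi_hat = ev$phi, residuals = ev$residuals,
    u_trace = run$u_trace, basins = basins,
    modes = spec$modes
  ), class = "global_fit")
}

# Jacobian of stepwise log K with respect to cumulative log beta, restricted
# to the refined parameters (fixed constants contribute no uncertainty).
.stepwise_transform <- function(model, refine) {
  cx <- complex_species(model)
  A <- diag(length(refine))
  rownames(A) <- colnames(A) <- refine
  for (nm in refine) {
    i <- match(nm, cx$name)
    if (cx$s[i] == 1L && cx$q[i] > 1L) {
      prev <- cx$name[cx$s == 1L & cx$q == cx$q[i] - 1L]
      if (length(prev) == 1L && prev %in% refine)
        A[nm, prev] <- -1
    }
  }
  A
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Global multiwavelength fit\n")
  if (!x$converged) cat("!! WARNING: fit did not converge\n")
  cat(sprintf("  modes: %s   solutions: %d   wavelengths: %d\n",
              paste(x$modes, collapse = ", "), x$ns, x$nw))
  for (nm in names(x$log_k)) {
    tag <- if (nm %in% x$refined) "" else "  (fixed)"
    cat(sprintf("  log K(%s) = %s%s\n", nm,
                format_constant(x$log_k[[nm]], x$se_log_k[[nm]]), tag))
  }
  cat(sprintf("  U = %.6g   sd(residual) = %.4g   iterations = %d\n",
              x$U, x$sd_residual, x$iterations))
  invisible(x)
}

#' Sum-of-squares objective of a model against a dataset
#'
#' `U = sum over modes, solutions and wavelengths of
#' (If_exp - If_calc)^2`, with the calculated intensities built from the
#' model's speciation and the supplied molar fluorescences.
#'
#' @param model an [equilibrium_model()].
#' @param data a `titration_dataset`.
#' @param phi named list (per mode) of species x wavelength molar
#'   fluorescence matrices.
#' @param modes modes to include; default all modes present in `phi`.
#' @param weights optional named per-mode weights.
#' @return the scalar objective `U`.
#' @export
objective_U <- function(model, data, phi, modes = names(phi), weights = NULL) {
  stopifnot(inherits(data, "titration_dataset"), is.list(phi))
  comp <- dataset_compositions_molar(data)
  ser <- speciation_series(model, comp)
  U <- 0
  for (md in modes) {
    C <- species_concentrations(ser, model)
    P <- phi[[md]]
    Ccols <- C[, rownames(P), drop = FALSE]
    w <- if (is.null(weights)) 1 else weights[[md]]
    U <- U + w * sum((data$spectra[[md]] - Ccols %*% P)^2)
  }
  U
}

#' Staged fit: constants from a mode subset are fixed, the rest re-refined
#'
#' Two-stage procedure for drugs whose very intense spectra in one mode
#' prevent a clean joint fit: stage 1 refines constants on a subset of modes
#' (e.g. emission + sync15, leaving out an overwhelming sync60 signal); the
#' stage-1 values of every species *not* refined again in stage 2 are then
#' fixed, and stage 2 refines its own constants on (possibly) all modes,
#' warm-started from stage 1.  The canonical use fits both constants of a
#' 1:1 + 1:2 model in stage 1, fixes the 1:1 value, and recalculates the 1:2
#' constant with all three modes.
#'
#' @param spec_stage1,spec_stage2 [fit_spec()] objects on the same model
#'   family; stage 1 must refine at least one species that stage 2 fixes.
#' @param data a `titration_dataset`.
#' @return the stage-2 `global_fit`, with `$stage1` (the stage-1 fit) and
#'   `$provenance` (which constant was fixed where) attached.
#' @export
staged_fit <- function(spec_stage1, spec_stage2, data) {
  stopifnot(inherits(spec_stage1, "fit_spec"), inherits(spec_stage2, "fit_spec"))
  fixed <- setdiff(spec_stage1$refine, spec_stage2$refine)
  if (!length(fixed))
    stop("stage 2 re-refines every stage-1 constant; nothing is fixed, ",
         "use refine_constants() directly")
  r1 <- refine_constants(spec_stage1, data)
  spec_stage2$model <- set_log_beta(spec_stage2$model,
                                    r1$log_beta[spec_stage1$refine])
  carried <- intersect(spec_stage1$refine, spec_stage2$refine)
  if (length(carried)) {
    start <- stats::setNames(r1$log_k[carried], carried)
    keep <- names(spec_stage2$start)[!names(spec_stage2$start) %in% carried]
    spec_stage2$start <- c(spec_stage2$start[keep], start)
  }
  r2 <- refine_constants(spec_stage2, data)
  r2$stage1 <- r1
  r2$provenance <- data.frame(
    species = c(fixed, spec_stage2$refine),
    stage = c(rep(1L, length(fixed)), rep(2L, length(spec_stage2$refine))),
    fixed_in_stage2 = c(rep(TRUE, length(fixed)),
                        rep(FALSE, length(spec_stage2$refine))))
  # carry stage-1 uncertainty for the fixed constant(s) in the report
  r2$se_log_k[fixed] <- r1$se_log_k[fixed]
  r2
}

#' Rank fitted models on the same dataset
#'
#' Orders candidate fits by residual standard deviation.  When a model with
#' fewer refined constants is within `factor` (relative) of the best
#' `sd_residual`, parsimony promotes it: the extra constant does not earn its
#' keep.  No species is ever deleted; the ranking is a report.
#'
#' @param results list of `global_fit` objects fitted to the same dataset.
#' @param labels optional names for the candidates.
#' @param factor relative `sd_residual` improvement an extra constant must
#'   exceed to beat a simpler model (default 5 %).
#' @return data.frame of class `model_ranking`, best first.
#' @export
compare_models <- function(results, labels = NULL, factor = 0.05) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "global_fit")))
  if (is.null(labels))
    labels <- vapply(results, function(r)
      paste(names(r$log_k), collapse = "+"), "")
  tab <- data.frame(
    model = labels,
    n_constants = vapply(results, function(r) length(r$log_k), 0L),
    U = vapply(results, function(r) r$U, 0),
    sd_residual = vapply(results, function(r) r$sd_residual, 0),
    converged = vapply(results, function(r) r$converged, TRUE))
  tab <- tab[order(tab$sd_residual), , drop = FALSE]
  best_sd <- tab$sd_residual[1]
  within <- tab$sd_residual <= best_sd * (1 + factor)
  tab$note <- ""
  if (sum(within) > 1) {
    simplest <- which(within)[which.min(tab$n_constants[within])]
    if (simplest != 1) {
      tab <- tab[c(simplest, setdiff(seq_len(nrow(tab)), simplest)), ]
      tab$note[1] <- sprintf(
        "preferred by parsimony: extra constant(s) improve sd_residual by < %g%%",
        100 * factor)
    }
  }
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("model_ranking", "data.frame")
  tab
}
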