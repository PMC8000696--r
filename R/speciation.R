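# Mass-balance speciation: free and complex concentrations of every species
# for given total concentrations.  Solved by Newton-Raphson in log free
# concentration space (positivity by construction) with damped steps.

solver_failure <- function(message, residual) {
  stop(structure(class = c("quenchfit_solver_error", "error", "condition"),
                 list(message = sprintf("%s (last residual %.3e)", message, residual),
                      call = sys.call(-1), residual = residual)))
}

#' Solution composition for one titration point
#'
#' @param total_s,total_q total (analytical) concentrations, mol/L.
#' @param temperature degrees Celsius.
#' @return an object of class `solution_composition` (a one-row list).
#' @export
solution_composition <- function(total_s, total_q, temperature = 25) {
  if (!is.finite(total_s) || total_s <= 0)
    stop("total_s must be a positive concentration (mol/L)")
  if (!is.finite(total_q) || total_q < 0)
    stop("total_q must be a non-negative concentration (mol/L)")
  structure(list(total_s = total_s, total_q = total_q,
                 temperature = temperature),
            class = "solution_composition")
}

#' Solve the component mass balances of a binding model
#'
#' Computes the equilibrium concentration of every species (free S, free Q
#' and all complexes) for one solution, i.e. finds free concentrations such
#' that `total_S = sum(s_i C_i)` and `total_Q = sum(q_i C_i)` with
#' `C_i = beta_i [S]^s_i [Q]^q_i`.
#'
#' Newton-Raphson on `(ln[S], ln[Q])`, which keeps all concentrations
#' positive; a step is halved (up to 20 times) whenever it increases the
#' worse of the two relative mass-balance errors.  `total_q = 0` is handled
#' analytically (no ligand-containing species can form).
#'
#' @param model an [equilibrium_model()].
#' @param total_s,total_q totals in mol/L; alternatively pass a
#'   [solution_composition()] as `total_s`.
#' @param tol relative mass-balance tolerance (both components).
#' @param max_iter maximum Newton iterations.
#' @param start optional starting free concentrations `c(S=, Q=)` (mol/L).
#' @return a `speciation` object: `free` (named, mol/L), `complexes`
#'   (named, mol/L), `residual` (max relative mass-balance error),
#'   `iterations`.
#' @examples
#' m <- equilibrium_model(6)        # 1:1, log Kb = 6
#' sp <- solve_mass_balance(m, 1e-6, 1e-6)
#' sp$complexes                     # 0.381966 uM, the quadratic root
#' @export
solve_mass_balance <- function(model, total_s, total_q = NULL, tol = 1e-10,
                               max_iter = 100L, start = NULL) {
  if (inherits(total_s, "solution_composition")) {
    total_q <- total_s$total_q
    total_s <- total_s$total_s
  }
  if (!is.finite(total_s) || total_s <= 0)
    stop("total_s must be a positive concentration (mol/L)")
  if (!is.finite(total_q) || total_q < 0)
    stop("total_q must be a non-negative concentration (mol/L)")
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0")

  sp <- model$species
  cx <- complex_species(model)
  result <- function(S, Q, C_complex, residual, iterations) {
    structure(list(free = c(S = S, Q = Q),
                   complexes = stats::setNames(C_complex, cx$name),
                   residual = residual, iterations = iterations),
              class = "speciation")
  }

  if (total_q == 0) {
    # every ligand-containing species is absent; S-only polymers are outside
    # this package's scope (one macromolecule binding site model family)
    if (any(cx$q == 0))
      stop("ligand-free complexes are not supported")
    return(result(total_s, 0, rep(0, nrow(cx)), 0, 0L))
  }

  s <- sp$s; q <- sp$q
  lbeta <- sp$log_beta * log(10)           # natural-log scale
  conc <- function(lnS, lnQ) exp(lbeta + s * lnS + q * lnQ)
  relerr <- function(C) {
    max(abs(sum(s * C) - total_s) / total_s,
        abs(sum(q * C) - total_q) / total_q)
  }

  if (!is.null(start)) {
    lnS <- log(start[["S"]]); lnQ <- log(start[["Q"]])
  } else {
    lnS <- log(total_s); lnQ <- log(total_q)
  }
  C <- conc(lnS, lnQ)
  err <- relerr(C)
  iter <- 0L
  while (err >= tol && iter < max_iter) {
    iter <- iter + 1L
    g <- c(sum(s * C) - total_s, sum(q * C) - total_q)
    J <- matrix(c(sum(s * s * C), sum(s * q * C),
                  sum(s * q * C), sum(q * q * C)), 2, 2)
    delta <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta)))
      solver_failure("singular Jacobian in mass-balance solve", err)
    # clamp to avoid overflow from wild early steps
    mx <- max(abs(delta))
    if (mx > 5) delta <- delta * (5 / mx)
    lam <- 1
    repeat {
      C_new <- conc(lnS + lam * delta[1], lnQ + lam * delta[2])
      err_new <- relerr(C_new)
      if (err_new < err || lam < 2^-20) break
      lam <- lam / 2
    }
    lnS <- lnS + lam * delta[1]; lnQ <- lnQ + lam * delta[2]
    C <- C_new; err <- err_new
  }
  if (err >= tol)
    solver_failure(sprintf("mass balance did not converge in %d iterations", max_iter), err)
  is_free <- (s == 1 & q == 0) | (s == 0 & q == 1)
  result(exp(lnS), exp(lnQ), C[!is_free], err, iter)
}

#' @export
print.speciation <- function(x, ...) {
  cat("Speciation (mol/L):\n")
  print(c(x$free, x$complexes))
  cat(sprintf("max relative mass-balance error: %.2e (%d iterations)\n",
              x$residual, x$iterations))
  invisible(x)
}

#' Solve the mass balances along a titration series
#'
#' Equivalent to calling [solve_mass_balance()] point by point; each point is
#' warm-started from the previous solution (speed only, same answers).
#'
#' @param model an [equilibrium_model()].
#' @param compositions a data.frame with columns `total_s` and `total_q`
#'   (mol/L), or a list of [solution_composition()] objects.
#' @inheritParams solve_mass_balance
#' @return a `speciation_series`: list of `speciation` objects.
#' @export
speciation_series <- function(model, compositions, tol = 1e-10, max_iter = 100L) {
  if (is.list(compositions) && !is.data.frame(compositions) &&
      all(vapply(compositions, inherits, TRUE, "solution_composition"))) {
    compositions <- data.frame(
      total_s = vapply(compositions, `[[`, 0, "total_s"),
      total_q = vapply(compositions, `[[`, 0, "total_q"))
  }
  n <- nrow(compositions)
  if (is.null(n) || n < 1) stop("at least one composition is required")
  out <- vector("list", n)
  start <- NULL
  for (i in seq_len(n)) {
    out[[i]] <- tryCatch(
      solve_mass_balance(model, compositions$total_s[i], compositions$total_q[i],
                         tol = tol, max_iter = max_iter, start = start),
      error = function(e) {
        stop(sprintf("speciation failed at titration point %d: %s", i,
                     conditionMessage(e)), call. = FALSE)
      })
    if (out[[i]]$free[["Q"]] > 0) start <- out[[i]]$free
  }
  structure(out, class = "speciation_series")
}

#' Species concentration matrix of a titration
#'
#' @param series a `speciation_series`.
#' @param model the model used to produce it.
#' @param fluorescent_only keep only fluorescent species (the design matrix
#'   of the molar-fluorescence linear solve).
#' @return matrix (solutions x species), mol/L, species names as colnames.
#' @export
species_concentrations <- function(series, model, fluorescent_only = FALSE) {
  sp <- model$species
  mat <- t(vapply(series, function(x) {
    v <- c(x$free, x$complexes)
    v[sp$name]
  }, numeric(nrow(sp))))
  colnames(mat) <- sp$name
  if (fluorescent_only) mat <- mat[, sp$fluorescent, drop = FALSE]
  mat
}
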