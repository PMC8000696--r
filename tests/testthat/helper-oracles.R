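# Independent speciation oracles, used to cross-check the Newton solver.

# closed-form 1:1 complex concentration (quadratic in [SQ])
oracle_complex_11 <- function(log_k, total_s, total_q) {
  K <- 10^log_k
  b <- total_s + total_q + 1 / K
  (b - sqrt(b^2 - 4 * total_s * total_q)) / 2
}

# nested bisection for an S + Q ladder (SQ and optionally SQ2), cumulative
# constants; free Q is the outer unknown, free S eliminated analytically
oracle_speciation_ladder <- function(log_beta, total_s, total_q,
                                     tol = 1e-15, iters = 200) {
  beta <- 10^log_beta
  b1 <- beta[1]
  b2 <- if (length(beta) > 1) beta[2] else 0
  free_s <- function(Q) total_s / (1 + b1 * Q + b2 * Q^2)
  g <- function(Q) Q + free_s(Q) * (b1 * Q + 2 * b2 * Q^2) - total_q
  lo <- 0; hi <- total_q
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol * max(total_q, 1e-30)) break
  }
  Q <- (lo + hi) / 2
  S <- free_s(Q)
  list(S = S, Q = Q, SQ = b1 * S * Q, SQ2 = b2 * S * Q^2)
}

# quick simulated dataset from a preset (small grid unless stated otherwise)
sim_preset <- function(preset, seed, temperature = 20, noise = NULL,
                       step = 1, keep_clean = FALSE) {
  pr <- drug_presets(temperature)[[preset]]
  truth <- pr$truth
  if (!is.null(noise)) truth$noise_sd_fraction <- noise
  proto <- preset_protocol(pr, seed = seed, temperature = temperature,
                           wavelength_step = step)
  list(ds = simulate_titration(proto, truth, keep_clean = keep_clean),
       truth = truth, model = truth$model, protocol = proto)
}
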