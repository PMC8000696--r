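# Binding-model construction and the mass-balance solver.

test_that("stepwise constants accumulate to cumulative ones and back", {
  m <- equilibrium_model(c(5.74, 4.57))
  expect_equal(unname(log_beta(m)), c(5.74, 5.74 + 4.57))
  expect_equal(unname(stepwise_log_k(m)), c(5.74, 4.57))
  m2 <- set_log_beta(m, c(SQ = 5.0, SQ2 = 4.0), constants = "stepwise")
  expect_equal(unname(log_beta(m2)), c(5.0, 9.0))
})

test_that("model validation rejects malformed complex lists", {
  expect_error(equilibrium_model(data.frame(s = 0, q = 0, log_k = 1)),
               "s \\+ q")
  expect_error(equilibrium_model(data.frame(s = c(1, 1), q = c(1, 1),
                                            log_k = c(5, 6))),
               "duplicate")
  expect_error(equilibrium_model(data.frame(s = 1, q = 0, log_k = 2)),
               "implicit")
  expect_error(
    equilibrium_model(data.frame(s = 2, q = 1, log_k = 5),
                      constants = "stepwise"),
    "ladder")
})

test_that("model JSON round-trips through both constant conventions", {
  m <- equilibrium_model(c(4.91, 5.53), fluorescent_free = c(S = TRUE, Q = TRUE))
  for (conv in c("stepwise", "cumulative")) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path, constants = conv)
    m2 <- read_model(path)
    expect_equal(log_beta(m2), log_beta(m), tolerance = 1e-12)
    expect_equal(m2$species$fluorescent, m$species$fluorescent)
  }
})

test_that("with no equilibria free concentrations equal the totals", {
  m <- equilibrium_model()
  sp <- solve_mass_balance(m, 3e-6, 10e-6)
  expect_equal(unname(sp$free), c(3e-6, 10e-6), tolerance = 1e-14)
  expect_length(sp$complexes, 0)
})

test_that("1:1 speciation matches the closed-form quadratic", {
  # log K = 6, both totals 1 uM: x^2 - 3x + 1 = 0 in uM units
  m <- equilibrium_model(6)
  sp <- solve_mass_balance(m, 1e-6, 1e-6)
  expect_equal(unname(sp$complexes["SQ"]), 0.381966011e-6, tolerance = 1e-8)
  expect_equal(unname(sp$free[["S"]]), 0.618033989e-6, tolerance = 1e-8)
  # against the oracle on a grid of conditions
  for (lk in c(4, 5.2, 6.5)) {
    m <- equilibrium_model(lk)
    for (r in c(0.3, 1, 5, 14)) {
      st <- 4.5e-6; qt <- r * st
      sp <- solve_mass_balance(m, st, qt)
      expect_equal(unname(sp$complexes["SQ"]), oracle_complex_11(lk, st, qt),
                   tolerance = 1e-10)
    }
  }
})

test_that("two-step ladder speciation matches the nested-bisection oracle", {
  m <- equilibrium_model(c(5.74, 4.57))
  sp <- solve_mass_balance(m, 4.5e-6, 30e-6)
  or <- oracle_speciation_ladder(c(5.74, 5.74 + 4.57), 4.5e-6, 30e-6)
  expect_equal(unname(sp$free[["S"]]), or$S, tolerance = 1e-8)
  expect_equal(unname(sp$free[["Q"]]), or$Q, tolerance = 1e-8)
  expect_equal(unname(sp$complexes[["SQ"]]), or$SQ, tolerance = 1e-8)
  expect_equal(unname(sp$complexes[["SQ2"]]), or$SQ2, tolerance = 1e-8)
})

test_that("solved points conserve mass and stay positive", {
  set.seed(42)
  m <- equilibrium_model(c(5.5, 4.8))
  sq <- complex_species(m)
  for (i in 1:25) {
    st <- runif(1, 0.5, 8) * 1e-6
    qt <- runif(1, 0.01, 20) * st
    sp <- solve_mass_balance(m, st, qt, tol = 1e-10)
    conc <- c(sp$free, sp$complexes)
    expect_true(all(conc >= 0))
    ts <- sum(c(1, 0, sq$s) * conc[c("S", "Q", sq$name)])
    tq <- sum(c(0, 1, sq$q) * conc[c("S", "Q", sq$name)])
    expect_lt(abs(ts - st) / st, 1e-10)
    expect_lt(abs(tq - qt) / qt, 1e-10)
  }
})

test_that("raising the 1:1 constant strictly raises the complex", {
  lks <- seq(3, 7, by = 0.5)
  sq <- vapply(lks, function(lk)
    solve_mass_balance(equilibrium_model(lk), 3e-6, 9e-6)$complexes[["SQ"]],
    0)
  expect_true(all(diff(sq) > 0))
})

test_that("zero quencher gives zero complexes analytically", {
  m <- equilibrium_model(c(5.74, 4.57))
  sp <- solve_mass_balance(m, 3e-6, 0)
  expect_identical(unname(sp$complexes), c(0, 0))
  expect_identical(sp$iterations, 0L)
})

test_that("invalid totals are rejected", {
  m <- equilibrium_model(5)
  expect_error(solve_mass_balance(m, 0, 1e-6), "positive")
  expect_error(solve_mass_balance(m, -1e-6, 1e-6), "positive")
  expect_error(solve_mass_balance(m, 1e-6, -1e-6), "non-negative")
})

test_that("a titration series equals point-by-point solutions", {
  m <- equilibrium_model(5)
  comp <- data.frame(total_s = rep(3e-6, 17),
                     total_q = c(0, seq(1, 40, length.out = 16)) * 1e-6)
  ser <- speciation_series(m, comp)
  for (i in seq_len(nrow(comp))) {
    one <- solve_mass_balance(m, comp$total_s[i], comp$total_q[i])
    # warm-starting affects the iteration path, not the solution
    expect_equal(unname(ser[[i]]$free), unname(one$free), tolerance = 1e-9)
    expect_equal(unname(ser[[i]]$complexes), unname(one$complexes),
                 tolerance = 1e-9)
  }
  expect_identical(unname(ser[[1]]$complexes), 0)
})

test_that("series failures carry the failing point index", {
  m <- equilibrium_model(5)
  comp <- data.frame(total_s = c(3e-6, -1e-6), total_q = c(1e-6, 1e-6))
  expect_error(speciation_series(m, comp), "point 2")
})

test_that("scaling both totals moves all concentrations continuously", {
  m <- equilibrium_model(c(5.74, 4.57))
  alphas <- c(0.5, 0.9, 1, 1.1, 2)
  conc <- sapply(alphas, function(a)
    c(solve_mass_balance(m, a * 4.5e-6, a * 20e-6)$complexes))
  # smoke property: monotone in the scale factor, no jumps
  expect_true(all(diff(conc["SQ", ]) > 0))
  expect_true(all(diff(conc["SQ2", ]) > 0))
})
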