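# Toggle switch model: Hill kinetics, ODE/SDE simulation, Jacobian and
# steady-state utilities.

test_that("decreasing Hill function obeys its defining identities", {
  expect_equal(hill(0, 30, 2), 1)
  expect_equal(hill(30, 30, 2), 0.5)
  expect_equal(hill(9.06e-2, 9.06e-2, 2), 0.5)
  # independent scalar arithmetic at the aTc threshold/coefficient
  expect_equal(hill(25, 11.65, 2), 0.178412627469, tolerance = 1e-10)
  # strictly decreasing
  x <- seq(0, 100, by = 0.5)
  expect_true(all(diff(hill(x, 31.94, 2)) < 0))
  expect_error(hill(-1, 30, 2), "requires")
  expect_error(hill(1, -30, 2), "requires")
  expect_error(hill(1, 30, 0), "requires")
})

test_that("toggle parameters validate and override", {
  p <- toggle_params()
  expect_length(unlist(unclass(p)), 22)
  expect_equal(p$thetaIPTG, 9.06e-2)
  expect_equal(toggle_params(kTm = 1)$kTm, 1)
  expect_error(toggle_params(kTm = -1), "positive")
  expect_error(toggle_params(nonsense = 2), "unknown")
})

test_that("vector field limits are forced by the kinetics", {
  p <- toggle_params()
  # zero state, zero inputs: full derepression of both promoters,
  # no degradation flux
  f <- toggle_rhs(toggle_state(), 0, 0, p)
  expect_equal(f[["mRNA_LacI"]], 8.332)
  expect_equal(f[["mRNA_TetR"]], 2.179)
  expect_equal(f[["LacI"]], 0)
  # equal internal/external aTc: no aTc exchange flux
  s <- toggle_state(TetR = 100, aTc_in = 25)
  expect_equal(toggle_rhs(s, 25, 0, p)[["aTc_in"]], 0)
})

test_that("Langevin drift equals the deterministic vector field", {
  p <- toggle_params()
  S <- togglecbc:::toggle_stoichiometry()
  set.seed(42)
  for (i in 1:20) {
    s <- toggle_state(mRNA_LacI = runif(1, 0, 60), mRNA_TetR = runif(1, 0, 20),
                      LacI = runif(1, 0, 3500), TetR = runif(1, 0, 1200),
                      aTc_in = runif(1, 0, 40), IPTG_in = runif(1, 0, 1))
    a <- propensities(s, 25, 0.3, p)
    expect_true(all(a >= 0))
    f <- toggle_rhs(s, 25, 0.3, p)
    expect_equal(as.numeric(S %*% a), as.numeric(f[1:4]), tolerance = 1e-12)
  }
})

test_that("propensities follow mass action and reject bad states", {
  p <- toggle_params()
  a0 <- propensities(toggle_state(), 0, 0, p)
  expect_true(all(a0[c("tx_LacI", "tx_TetR")] > 0))
  expect_true(all(a0[-(1:2)] == 0))
  a <- propensities(toggle_state(LacI = 100), 0, 0, p)
  expect_equal(a[["deg_LacI"]], p$gLp * 100)
  s <- toggle_state(); s[3] <- -1
  expect_error(propensities(s, 0, 0, p), "negative")
})

test_that("ODE simulation holds equilibria and is grid-consistent", {
  p <- toggle_params()
  eq <- steady_state(p, 25, 0, toggle_state(mRNA_LacI = 50, mRNA_TetR = 1,
                                            LacI = 3000, TetR = 60))
  tr <- simulate_toggle_ode(p, c(aTc_ext = 25, IPTG_ext = 0), eq,
                            t_end = 300)
  expect_lt(max(abs(tr$TetR - eq[["TetR"]])), 1e-4)
  expect_true(all(as.matrix(tr[, 2:7]) >= 0))
  # long simulation from a generic state reaches the bracketing oracle's
  # stable root
  tr2 <- simulate_toggle_ode(p, c(aTc_ext = 25, IPTG_ext = 0),
                             toggle_state(TetR = 400, LacI = 400),
                             t_end = 3000)
  root <- oracle_roots(0)[[1]]
  expect_equal(utils::tail(tr2$TetR, 1), root[["TetR"]], tolerance = 1e-4)
  expect_equal(utils::tail(tr2$LacI, 1), root[["LacI"]], tolerance = 1e-4)
  # doubling the sampling density does not move shared samples
  tra <- simulate_toggle_ode(p, c(aTc_ext = 25, IPTG_ext = 0.3),
                             toggle_state(TetR = 400), t_end = 100,
                             sample_period = 5)
  trb <- simulate_toggle_ode(p, c(aTc_ext = 25, IPTG_ext = 0.3),
                             toggle_state(TetR = 400), t_end = 100,
                             sample_period = 2.5)
  shared <- trb$time_min %in% tra$time_min
  expect_equal(trb$TetR[shared], tra$TetR, tolerance = 1e-6)
})

test_that("SDE integrator is seeded, nonnegative, and degenerates to Euler", {
  p <- toggle_params()
  x0 <- toggle_state(mRNA_LacI = 10, mRNA_TetR = 2, LacI = 500, TetR = 200,
                     aTc_in = 25)
  a <- simulate_toggle_sde(p, c(aTc_ext = 25, IPTG_ext = 0.3), x0,
                           t_end = 100, seed = 7)
  b <- simulate_toggle_sde(p, c(aTc_ext = 25, IPTG_ext = 0.3), x0,
                           t_end = 100, seed = 7)
  expect_identical(a, b)
  expect_true(all(as.matrix(a[, 2:7]) >= 0))
  # zero noise amplitude: fixed-step deterministic Euler, re-derived
  # independently here
  z <- simulate_toggle_sde(p, c(aTc_ext = 25, IPTG_ext = 0.3), x0,
                           t_end = 20, dt = 0.1, seed = 1, noise_scale = 0)
  x <- as.numeric(x0)
  S <- togglecbc:::toggle_stoichiometry()
  for (i in seq_len(200)) {
    f4 <- S %*% propensities(x, 25, 0.3, p)
    x5 <- x[5] + p$kaTcin * (25 - x[5]) * 0.1
    x6 <- x[6] + p$kIPTGin * (0.3 - x[6]) * 0.1
    x <- c(pmax(x[1:4] + f4 * 0.1, 0), x5, x6)
  }
  expect_equal(as.numeric(z[5, 2:7]), x, tolerance = 1e-10)
})

test_that("ensemble mean of the SDE tracks the ODE in a monostable regime", {
  # high-abundance regime (high-TetR branch, IPTG = 0.8 is monostable)
  # where the chemical Langevin approximation is quantitative; at low
  # copy numbers the zero-clamp biases small species upward by design
  p <- toggle_params()
  x0 <- steady_state(p, 25, 0.8, toggle_state(mRNA_LacI = 2,
                                              mRNA_TetR = 16,
                                              LacI = 90, TetR = 1100))
  det <- simulate_toggle_ode(p, c(aTc_ext = 25, IPTG_ext = 0.8), x0,
                             t_end = 200)
  ens <- vapply(1:40, function(s) {
    tr <- simulate_toggle_sde(p, c(aTc_ext = 25, IPTG_ext = 0.8), x0,
                              t_end = 200, seed = s)
    utils::tail(tr$TetR, 1)
  }, numeric(1))
  det_T <- utils::tail(det$TetR, 1)
  expect_lt(abs(mean(ens) - det_T) / det_T,
            3 * sd(ens) / sqrt(40) / det_T + 0.02)
})

test_that("analytic Jacobian matches central differences and flags stability", {
  p <- toggle_params()
  set.seed(3)
  for (i in 1:10) {
    s <- toggle_state(mRNA_LacI = runif(1, 1, 60), mRNA_TetR = runif(1, 0.1, 20),
                      LacI = runif(1, 10, 3500), TetR = runif(1, 10, 1200),
                      aTc_in = runif(1, 1, 40), IPTG_in = runif(1, 0.01, 1))
    Ja <- toggle_jacobian(s, 25, 0.3, p)
    Jf <- togglecbc:::fd_jacobian(s, 25, 0.3, p)
    expect_lt(max(abs(Ja - Jf)) / max(abs(Ja)), 1e-5)
    expect_equal(unname(diag(Ja)[1:4]), -c(p$gLm, p$gTm, p$gLp, p$gTp))
  }
  eq <- steady_state(p, 25, 0, toggle_state(mRNA_LacI = 50, mRNA_TetR = 1,
                                            LacI = 3000, TetR = 60))
  ev <- eigen(toggle_jacobian(eq, 25, 0, p))$values
  expect_true(all(Re(ev) < 0))
})

test_that("steady states satisfy the residual contract and bracket bistability", {
  p <- toggle_params()
  eq <- steady_state(p, 25, 0.3, toggle_state(TetR = 60, LacI = 3000,
                                              mRNA_LacI = 50, mRNA_TetR = 1))
  f <- toggle_rhs(eq, 25, 0.3, p)
  expect_lt(sqrt(sum(f^2)), 1e-9)
  expect_equal(eq[["aTc_in"]], 25)
  expect_equal(eq[["IPTG_in"]], 0.3)
  # in the bistable window, low- and high-TetR guesses give distinct roots
  lo <- steady_state(p, 25, 0.3, toggle_state(TetR = 60, LacI = 3000,
                                              mRNA_LacI = 50, mRNA_TetR = 1))
  hi <- steady_state(p, 25, 0.3, toggle_state(TetR = 1100, LacI = 90,
                                              mRNA_LacI = 2, mRNA_TetR = 16))
  expect_gt(hi[["TetR"]] - lo[["TetR"]], 500)
  expect_error(steady_state(p, 25, 0.3, toggle_state(), max_iter = 1),
               "converge")
})
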