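# Steady-state parameter estimation: analytic inverse, nearest-point
# cost, genetic-algorithm fit, sweep baseline and bistability check.

test_that("the analytic inverse reproduces the continued curve", {
  bd <- nominal_diagram()
  keep <- bd$IPTG > 1e-4
  iv <- equilibrium_input(bd$TetR[keep], theta_nominal())
  rel <- abs(iv - bd$IPTG[keep]) / bd$IPTG[keep]
  expect_lt(max(rel), 1e-6)
})

test_that("forward steady state inverts the analytic inverse", {
  p <- nominal_params()
  bd <- nominal_diagram()
  for (Tt in c(100, 250, 400, 700, 1000)) {
    iptg <- equilibrium_input(Tt, theta_nominal())
    g <- diagram_state_at(bd, Tt)
    eq <- steady_state(p, 25, iptg, c(g, 25, iptg))
    expect_equal(eq[["TetR"]], Tt, tolerance = 1e-6)
  }
  # below the leakage floor the required repression is unreachable
  expect_true(is.na(equilibrium_input(50, theta_nominal())))
  expect_true(is.na(equilibrium_input(60.88, theta_nominal())))
  expect_error(equilibrium_input(-5, theta_nominal()))
})

test_that("the nominal predicted curve is S-shaped and normalized", {
  grid <- seq(65, 1220, length.out = 800)
  cv <- predicted_curve(theta_nominal(), grid)
  # IPTG non-monotone in TetR with exactly two turning points
  s <- sign(diff(cv$IPTG))
  flips <- sum(diff(s[s != 0]) != 0)
  expect_equal(flips, 2)
  expect_lte(max(cv$IPTG_n), 1 + 1e-9)
  expect_equal(nrow(predicted_curve(theta_nominal(), 400)), 1)
  expect_error(predicted_curve(theta_nominal(), 10), "admissible")
})

test_that("nearest-point cost matches hand arithmetic and is permutation invariant", {
  # single measured point against a two-point curve: hand-computed
  # squared distances with norm constants TetR = 1000, IPTG = 1
  norm <- list(TetR = 1000, IPTG = 1)
  meas <- measured_points(500, 0.30, norm = norm)
  curve <- tibble::tibble(TetR_n = c(0.45, 0.60), IPTG_n = c(0.32, 0.25))
  d2 <- pmin((0.5 - 0.45)^2 + (0.30 - 0.32)^2,
             (0.5 - 0.60)^2 + (0.30 - 0.25)^2)
  # route the same pair through estimation_cost via a stubbed curve:
  # evaluate the internal distance rule directly
  d2_pkg <- min(outer(meas$TetR_n, curve$TetR_n, "-")^2 +
                  outer(meas$IPTG_n, curve$IPTG_n, "-")^2)
  expect_equal(d2_pkg, d2)
  # measured points on the nominal curve cost ~ 0 at nominal parameters
  grid <- seq(65, 1220, length.out = 2000)
  cv <- predicted_curve(theta_nominal(), grid)
  pick <- seq(10, nrow(cv), by = 97)
  meas2 <- measured_points(cv$TetR[pick], cv$IPTG[pick],
                           norm = list(TetR = max(cv$TetR), IPTG = 1))
  expect_lt(estimation_cost(theta_nominal(), meas2), 1e-4)
  # permutation invariance
  perm <- sample(length(pick))
  meas3 <- measured_points(cv$TetR[pick][perm], cv$IPTG[pick][perm],
                           norm = list(TetR = max(cv$TetR), IPTG = 1))
  expect_equal(estimation_cost(theta_nominal(), meas3),
               estimation_cost(theta_nominal(), meas2))
})

test_that("estimation is seeded and its cost trace is monotone", {
  grid <- seq(65, 1220, length.out = 600)
  cv <- predicted_curve(theta_nominal(), grid)
  pick <- seq(5, nrow(cv), by = 40)
  meas <- measured_points(cv$TetR[pick], cv$IPTG[pick])
  e1 <- estimate_parameters(meas, pop_size = 30, generations = 15, seed = 3)
  e2 <- estimate_parameters(meas, pop_size = 30, generations = 15, seed = 3)
  expect_identical(e1$theta, e2$theta)
  expect_true(all(diff(e1$trace$best) <= 0))
  expect_true(all(e1$theta > 0))
})

test_that("open-loop sweeps collect only stable branches and show hysteresis", {
  p <- nominal_params()
  levels <- seq(0, 0.6, by = 0.05)
  sw <- run_sweep(p, levels, plant = "ode")
  for (i in seq_len(nrow(sw))) {
    chk <- point_vs_oracle(sw$TetR_ss[i], sw$IPTG_ss[i])
    expect_lt(chk$rel, 0.01)
    expect_equal(chk$stability, "stable")
  }
  # no sweep point near the unstable branch
  bd <- nominal_diagram()
  unst <- bd[bd$stability == "unstable", ]
  for (i in seq_len(nrow(sw))) {
    du <- sqrt((unst$TetR / 1200 - sw$TetR_ss[i] / 1200)^2 +
                 (unst$IPTG - sw$IPTG_ss[i])^2)
    expect_gt(min(du), 0.02)
  }
  # ascending and descending orders disagree inside the bistable window
  folds <- attr(bd, "folds")
  mid <- levels[levels > min(folds$IPTG) & levels < max(folds$IPTG)]
  up <- sw[sw$direction == "ascending", ]
  dn <- sw[sw$direction == "descending", ]
  gap <- vapply(mid, function(l) {
    abs(up$TetR_ss[which.min(abs(up$IPTG_ss - l))] -
          dn$TetR_ss[which.min(abs(dn$IPTG_ss - l))])
  }, numeric(1))
  expect_gt(max(gap), 500)
})

test_that("bistability check flags the nominal model and not a crippled one", {
  expect_true(check_bistability(theta_nominal()))
  th <- theta_nominal()
  th["kTm"] <- th["kTm"] * 1e-3
  expect_false(suppressWarnings(check_bistability(th)))
  expect_equal(check_bistability(theta_nominal()),
               check_bistability(theta_nominal()))
})

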