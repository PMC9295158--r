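# Shared fixtures, computed once per test run and cached. All heavy
# objects (reference diagram, full CBC runs, identified model) are built
# here so unit and acceptance tests reuse the same computations.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, compute(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

nominal_params <- function() toggle_params()

# model-based reference curve at aTc = 25
nominal_diagram <- function() {
  fixture("diagram", function() continue_equilibria(nominal_params()))
}

# full deterministic CBC run with the proportional controller: the
# main-text protocol (30 references 1800 -> 0, fixed dwell 9 h 55 min)
cbc_run_p <- function() {
  fixture("cbc_p", function() {
    run_cbc(p_controller(Kp = 0.0016),
            cbc_config(ref_start = 1800, ref_end = 0, n_points = 30,
                       dwell_mode = "fixed", dwell = 595, plant = "ode"),
            nominal_params())
  })
}

# innovation-form model identified from stochastic pulse data
id_model <- function() {
  fixture("lti", function() {
    identify_lti(generate_id_data(nominal_params(), seed = 11), order = 4)
  })
}

# full deterministic CBC run with the MPC controller (reference range
# 1200 -> 0, gamma = 0.3)
cbc_run_mpc <- function() {
  fixture("cbc_mpc", function() {
    run_cbc(mpc_controller(id_model(), gamma = 0.3),
            cbc_config(ref_start = 1200, ref_end = 0, n_points = 30,
                       dwell_mode = "fixed", dwell = 595, plant = "ode",
                       seed = 5),
            nominal_params())
  })
}

# stochastic CBC repetitions (chemical Langevin plant, steady-state
# detection to shorten the dwell)
cbc_runs_sde <- function() {
  fixture("cbc_sde", function() {
    lapply(1:3, function(s) {
      run_cbc(p_controller(Kp = 0.0016),
              cbc_config(plant = "sde", dwell_mode = "detect", seed = s),
              nominal_params())
    })
  })
}

# all open-loop equilibrium TetR values at one IPTG, by exhaustive
# scalar bracketing (independent of the continuation code)
oracle_roots <- function(IPTG, params = nominal_params(), aTc = 25) {
  togglecbc:::equilibria_at(params, aTc, IPTG)
}

# 4-state vector of the diagram point nearest a TetR value, used as a
# Newton guess
diagram_state_at <- function(bd, TetR) {
  i <- which.min(abs(bd$TetR - TetR))
  as.numeric(bd[i, c("mRNA_LacI", "mRNA_TetR", "LacI", "TetR")])
}

# relative TetR distance from a collected point to the nearest
# open-loop equilibrium at its own IPTG_ss, plus that root's stability
point_vs_oracle <- function(TetR_ss, IPTG_ss, params = nominal_params()) {
  eqs <- oracle_roots(IPTG_ss, params)
  tet <- vapply(eqs, function(e) e[["TetR"]], numeric(1))
  j <- which.min(abs(tet - TetR_ss))
  list(rel = abs(tet[j] - TetR_ss) / max(TetR_ss, 1e-9),
       stability = classify_stability(eqs[[j]], 25, IPTG_ss, params))
}
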