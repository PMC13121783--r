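## Shared miniature fixtures for the unit tests.

## A hand-built symmetric bi-oriented spring-network state: poles at
## +/- 6 um, four kMTs of 5.4 um, every linker at its equilibrium load.
symmetric_state <- function(len_nm = 5400, kappa1 = 0.02) {
  mk <- function(id, pole, att) microtubule(id, "kMT", pole,
                                            minus_pos = if (pole == "L") -6000 else 6000,
                                            n_sites = round(len_nm / 8),
                                            attached_to = att)
  list(poles = c(L = -6000, R = 6000),
       kappa = list(kappa1 = kappa1, kappa2 = 0.1, kappa3 = 0.1),
       x0_nm = 500,
       mts = list(mk(1, "L", "L"), mk(2, "L", "L"),
                  mk(3, "R", "R"), mk(4, "R", "R")))
}

## Minimal object quacking like a spindle_sim for observable arithmetic.
fake_sim <- function(trans_t, trans_label, duration_s,
                     trajectory = NULL, N = 2L, d_nm = 8) {
  structure(list(transitions = data.frame(t_s = trans_t, label = trans_label),
                 duration_s = duration_s,
                 trajectory = trajectory,
                 sample_every_s = 1,
                 params = list(N = N, d_nm = d_nm, x0_um = 0.5)),
            class = "spindle_sim")
}

## Quiet params for fast deterministic runs: all stochastic machinery off.
frozen_params <- function(...) {
  spindle_params(eg5_enabled = FALSE, kif2a_enabled = FALSE,
                 numa_enabled = FALSE, detach_enabled = FALSE,
                 poly = polymerization_law(v_p0 = 1e-9, B = 2), ...)
}
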