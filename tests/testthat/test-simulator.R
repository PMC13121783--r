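test_that("presets build states with the advertised classification", {
  p <- spindle_params()
  cases <- list(bi_oriented = 0L, merotelic1 = 1L, merotelic2 = 2L,
                syntelic = 10L, monotelic = 11L)
  for (nm in names(cases)) {
    st <- make_initial_state(p, nm)
    att <- c("none", "L", "R")[st$attached[1:4] + 1]
    lab <- classify_attachment(c("L", "L", "R", "R"), att,
                               ever_attached = st$ever_attached[1:4])
    expect_equal(lab$code, cases[[nm]], info = nm)
  }
  ## type-III merotelic needs N >= 3
  expect_error(make_initial_state(p, "merotelic3"))
  p3 <- spindle_params(N = 3)
  st3 <- make_initial_state(p3, "merotelic3")
  att3 <- c("none", "L", "R")[st3$attached[1:6] + 1]
  expect_equal(classify_attachment(rep(c("L", "R"), each = 3), att3)$code, 3L)
  ## monotelic: exactly one sister attached, all its kMTs from one pole
  stm <- make_initial_state(p, "monotelic")
  attm <- c("none", "L", "R")[stm$attached[1:4] + 1]
  expect_equal(unique(attm[attm != "none"]), "R")
  expect_true(all(which(attm != "none") > 2))
})

test_that("identical (params, preset, seed) reproduce bit-identical runs", {
  p <- spindle_params()
  s1 <- simulate_spindle(p, "merotelic2", duration_s = 30, seed = 42)
  s2 <- simulate_spindle(p, "merotelic2", duration_s = 30, seed = 42)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$transitions, s2$transitions)
  s3 <- simulate_spindle(p, "merotelic2", duration_s = 30, seed = 43)
  expect_false(identical(s1$trajectory, s3$trajectory))
})

test_that("degenerate parameters leave everything but the clock unchanged", {
  p <- frozen_params()
  sim <- simulate_spindle(p, "bi_oriented", duration_s = 10, seed = 1)
  tr <- sim$trajectory
  expect_equal(nrow(tr), 11L)
  expect_equal(length(unique(tr$xL_nm)), 1L)
  expect_equal(length(unique(tr$len_nm_mt1)), 1L)
  expect_equal(sum(sim$removed), 0)
  expect_equal(nrow(sim$events), 0L)
  ## zero duration: only the initial sample
  sim0 <- simulate_spindle(p, "bi_oriented", duration_s = 0, seed = 1)
  expect_equal(nrow(sim0$trajectory), 1L)
})

test_that("the initial mechanical state matches the hand-solved balance", {
  p <- spindle_params()
  sim <- simulate_spindle(frozen_params(), "bi_oriented", duration_s = 1,
                          seed = 1)
  tr <- sim$trajectory[1, ]
  expect_equal(tr$xR_nm - tr$xL_nm - 500, 500, tolerance = 1e-6)
  expect_equal(unlist(tr[paste0("F_pN_k", 1:4)]), rep(5, 4),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a pinned single-site fixture reproduces the two-state occupancy", {
  ## constant attach/detach rates via frozen mechanics; compare the
  ## detached-time fraction of one kMT with the closed-form occupancy
  k_a <- attach_rate(100)              # 60.65 /s at 100 nm
  x_um <- 0.5
  k_d <- detach_rate(5, x_um)          # Aurora on at rest stretch
  p <- spindle_params(eg5_enabled = FALSE, kif2a_enabled = FALSE,
                      numa_enabled = FALSE,
                      poly = polymerization_law(v_p0 = 1e-9))
  sim <- simulate_spindle(p, "bi_oriented", duration_s = 600, seed = 9,
                          pin = list(F = 5, x_um = x_um, yL = 100, yR = 1e9))
  ## occupancy of kMT 1 from the event log
  ev <- sim$events[sim$events$mt == 1, ]
  t_det <- 0
  td <- ev$t_s[ev$type == "detach"]; ta <- ev$t_s[ev$type == "attach"]
  for (i in seq_along(td)) {
    nxt <- ta[ta > td[i]][1]
    t_det <- t_det + (if (is.na(nxt)) 600 - td[i] else nxt - td[i])
  }
  occ <- 1 - t_det / 600
  p_inf <- k_a / (k_a + k_d)
  ## correlation-aware 3-sigma band for a two-state occupancy average
  var_occ <- 2 * p_inf * (1 - p_inf)^2 / (k_d * 600) # spectral approximation
  expect_lt(abs(occ - p_inf), 3 * sqrt(var_occ) + 1e-4)
  expect_gt(nrow(ev), 10)  # the chain actually switched many times
})

test_that("detachment events and reattachments alternate per microtubule", {
  p <- spindle_params()
  sim <- simulate_spindle(p, "merotelic2", duration_s = 400, seed = 5)
  for (k in unique(sim$events$mt)) {
    ev <- sim$events[sim$events$mt == k, ]
    types <- ev$type
    ## starts attached, so the first event is a detachment, then strict
    ## alternation; a trailing detachment may be open at the run end
    expect_equal(types[1], "detach")
    expect_true(all(types[seq_along(types) %% 2 == 1] == "detach"))
    expect_true(all(types[seq_along(types) %% 2 == 0] == "attach"))
  }
  ## kMT count is conserved
  expect_equal(length(sim$final$n_sites), 8L)
})

test_that("Aurora ablation slows the escape from the merotelic state", {
  ## matched seeds, short horizon: first-passage times with Aurora on are
  ## collectively shorter than with Aurora off
  horizon <- 900
  fp <- function(aurora, seed) {
    p <- spindle_params(aurora_active = aurora)
    sim <- simulate_spindle(p, "merotelic2", duration_s = horizon, seed = seed)
    t <- first_passage_to_bi(sim)
    if (is.na(t$t_s)) horizon else t$t_s
  }
  seeds <- 1:6
  t_on <- vapply(seeds, function(s) fp(TRUE, s), numeric(1))
  t_off <- vapply(seeds, function(s) fp(FALSE, s), numeric(1))
  expect_lt(mean(t_on), mean(t_off))
})
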