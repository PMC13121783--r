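test_that("attachment classification is total over all assignments", {
  ## every assignment of {none, L, R} to the four kMTs of an N = 2 spindle
  ## gets exactly one label
  pole <- c("L", "L", "R", "R")
  opts <- c("none", "L", "R")
  grid <- expand.grid(k1 = opts, k2 = opts, k3 = opts, k4 = opts,
                      stringsAsFactors = FALSE)
  labs <- apply(grid, 1, function(a) classify_attachment(pole, unname(a))$state)
  expect_equal(length(labs), 81L)
  expect_false(any(is.na(labs)))
  ## deterministic
  labs2 <- apply(grid, 1, function(a) classify_attachment(pole, unname(a))$state)
  expect_identical(labs, labs2)

  ## anchors of the taxonomy
  expect_equal(classify_attachment(pole, c("L", "L", "R", "R"))$state,
               "bi_oriented")
  expect_equal(classify_attachment(pole, c("R", "L", "R", "R"))$state,
               "merotelic1")
  expect_equal(classify_attachment(pole, c("R", "L", "R", "L"))$state,
               "merotelic2")
  expect_equal(classify_attachment(pole, c("none", "L", "R", "L"))$state,
               "detached")
  ## all attached from one pole
  expect_equal(classify_attachment(pole, c("none", "none", "L", "R"),
                                   ever_attached = c(FALSE, FALSE, TRUE, TRUE))$state,
               "syntelic")
  expect_equal(classify_attachment(pole, c("none", "none", "R", "R"),
                                   ever_attached = c(FALSE, FALSE, TRUE, TRUE))$state,
               "monotelic")
  ## never-attached stubs are excluded until first engagement
  expect_equal(classify_attachment(pole, rep("none", 4),
                                   ever_attached = rep(FALSE, 4))$state,
               "unengaged")
})

test_that("P_bi and first passage follow their definitions", {
  ## 90 s bi-oriented + 10 s merotelic-1 + 5 s detached -> 0.90
  sim <- fake_sim(trans_t = c(0, 30, 120, 130),
                  trans_label = c(2L, 0L, 1L, -1L), duration_s = 135)
  expect_equal(first_passage_to_bi(sim)$t_s, 30)
  expect_equal(p_bi(sim), 90 / 100)

  ## all bi-oriented
  sim2 <- fake_sim(0, 0L, 1000)
  expect_equal(p_bi(sim2), 1)
  expect_equal(first_passage_to_bi(sim2)$t_s, 0)

  ## synthetic sequence: merotelic2 (0-60), merotelic1 (60-90), BI (90-)
  sim3 <- fake_sim(c(0, 60, 90), c(2L, 1L, 0L), 200)
  expect_equal(first_passage_to_bi(sim3)$t_s, 90)

  ## never bi-oriented: censored, P_bi undefined
  sim4 <- fake_sim(0, 2L, 500)
  expect_true(first_passage_to_bi(sim4)$censored)
  expect_true(is.na(p_bi(sim4)))
})

test_that("detachment episodes are measured with their resolution state", {
  sim <- fake_sim(trans_t = c(0, 10, 20, 20.05, 50, 50.2),
                  trans_label = c(2L, 0L, -1L, 0L, -1L, 1L),
                  duration_s = 100)
  ep <- detachment_episodes(sim)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$duration_s, c(0.05, 0.2), tolerance = 1e-9)
  expect_equal(ep$next_label, c(0L, 1L))
  ## only episodes that return to bi-orientation
  ep_bi <- ep[ep$next_label == 0, ]
  expect_equal(mean(ep_bi$duration_s), 0.05, tolerance = 1e-9)
})

test_that("flux is removals per second times the site size", {
  tr <- data.frame(t_s = 0:700)
  for (k in 1:4) tr[[paste0("removed_mt", k)]] <- 2.5 * tr$t_s
  tr$xL_nm <- -500; tr$xR_nm <- 500
  sim <- fake_sim(0, 0L, 700, trajectory = tr)
  expect_equal(flux_rate(sim, t_start = 100, t_end = 700), 20)
  ## zero removal
  for (k in 1:4) tr[[paste0("removed_mt", k)]] <- 0
  sim0 <- fake_sim(0, 0L, 700, trajectory = tr)
  expect_equal(flux_rate(sim0, t_start = 100), 0)
  expect_error(flux_rate(sim, t_start = 650, t_end = 700))
})

test_that("DAP measures the centre deviation", {
  tr <- data.frame(t_s = 0:500, xL_nm = -500, xR_nm = 500)
  sim <- fake_sim(0, 0L, 500, trajectory = tr)
  expect_equal(dap(sim)$DAP_nm, 0)
  tr2 <- data.frame(t_s = 0:500, xL_nm = -200, xR_nm = 800)
  expect_equal(dap(fake_sim(0, 0L, 500, trajectory = tr2))$DAP_nm, 300)
})

test_that("the period estimator recovers noisy sinusoids to the sample bin", {
  set.seed(19)
  dt <- 4                                # 90 samples per 360-s cycle
  errs <- vapply(seq_len(100), function(i) {
    phase <- runif(1, 0, 2 * pi)
    t <- seq(0, 4796, by = dt)           # ~13 cycles
    x <- sin(2 * pi * t / 360 + phase) + rnorm(length(t), sd = 0.3)
    estimate_period(x, dt = dt) - 360
  }, numeric(1))
  expect_false(any(is.na(errs)))
  expect_true(all(abs(errs) <= dt))      # within one sample bin
  ## constant trace: undefined
  expect_true(is.na(estimate_period(rep(1, 400))))
})

test_that("force statistics summarise the attached plus-end forces", {
  tr <- data.frame(t_s = 0:200, xL_nm = -500, xR_nm = 500)
  for (k in 1:4) { tr[[paste0("F_pN_k", k)]] <- 5; tr[[paste0("att_k", k)]] <- 1 }
  sim <- fake_sim(0, 0L, 200, trajectory = tr)
  fs <- force_stats(sim, t_start = 0)
  expect_equal(fs$mean_F_pN, 5)
  expect_equal(fs$neg_force_freq, 0)
  tr$F_pN_k1 <- -2
  fs2 <- force_stats(fake_sim(0, 0L, 200, trajectory = tr), t_start = 0)
  expect_equal(fs2$neg_force_freq, 0.25)
  expect_equal(fs2$mean_F_pN, mean(c(-2, 5, 5, 5)))
})

test_that("event-log and sample-based P_bi agree on a real run", {
  p <- spindle_params()
  sim <- simulate_spindle(p, "merotelic2", duration_s = 900, seed = 12)
  pe <- p_bi(sim); ps <- p_bi_samples(sim)
  if (!is.na(pe) && !is.na(ps)) expect_lt(abs(pe - ps), 0.05)
  ## simulator labels match the standalone classifier at every sample
  n_kmt <- 4L
  att <- as.matrix(sim$trajectory[, paste0("att_k", 1:n_kmt)])
  pole <- c("L", "L", "R", "R")
  ever <- matrix(TRUE, nrow(att), n_kmt)  # merotelic start: all engaged
  idx <- seq(1, nrow(att), by = 37)
  for (i in idx) {
    lab <- classify_attachment(pole, c("none", "L", "R")[att[i, ] + 1])$code
    expect_equal(lab, sim$trajectory$label[i])
  }
})
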