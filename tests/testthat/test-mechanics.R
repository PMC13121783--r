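test_that("kMT polymerization law matches its anchor points", {
  law <- polymerization_law()
  expect_equal(kmt_polymerization_rate(0, TRUE, law), law$v_p0 / law$B)
  expect_equal(kmt_polymerization_rate(law$F_p0, TRUE, law),
               2 * law$v_p0 / law$B)
  expect_equal(kmt_polymerization_rate(12, FALSE, law), 20)
  ## pushing slows growth and stalls it at -F_p0
  expect_equal(kmt_polymerization_rate(-law$F_p0 / 2, TRUE, law),
               law$v_p0 / law$B / 2)
  expect_equal(kmt_polymerization_rate(-law$F_p0, TRUE, law), 0)
  expect_equal(kmt_polymerization_rate(-2 * law$F_p0, TRUE, law), 0)
  expect_error(polymerization_law(B = 1))
})

test_that("the symmetric bi-oriented balance gives kappa1*(x-x0) = 2F", {
  st <- symmetric_state()
  sol <- solve_static_positions(st)
  expect_lt(sol$residual, 1e-6)
  expect_equal(sol$x - 500, 500, tolerance = 1e-9)    # stretch 500 nm
  expect_equal(sol$F, rep(5, 4), tolerance = 1e-9)    # 5 pN each
  expect_equal(sum(sol$F[1:2]), 0.02 * (sol$x - 500), tolerance = 1e-9)
})

test_that("degenerate attachment topologies are handled", {
  ## nothing attached: positions held, forces zero
  st <- symmetric_state()
  for (i in 1:4) st$mts[[i]]$attached_to <- "none"
  st$prev <- list(xL = -123, xR = 377)
  sol <- solve_static_positions(st)
  expect_equal(sol$xL, -123); expect_equal(sol$xR, 377)
  expect_equal(sol$F, rep(0, 4))

  ## monotelic-like: only the right sister attached, all one pole;
  ## per-kMT forces sum to the (zero) sister-spring load
  st <- symmetric_state()
  st$mts[[1]]$attached_to <- "none"; st$mts[[2]]$attached_to <- "none"
  st$mts[[3]]$attached_to <- "R"; st$mts[[4]]$attached_to <- "R"
  st$mts[[4]]$n_sites <- st$mts[[4]]$n_sites + 25L   # unequal lengths
  sol <- solve_static_positions(st)
  expect_lt(sol$residual, 1e-6)
  expect_equal(sum(sol$F[3:4]), 0.02 * (sol$x - 500), tolerance = 1e-9)
  expect_equal(sol$x, 500, tolerance = 1e-9)          # no opposing pole
  expect_equal(sum(sol$F), 0, tolerance = 1e-9)

  ## syntelic-like: both sisters, one pole: net force on the pair is zero
  st <- symmetric_state()
  st$mts[[1]]$attached_to <- "none"; st$mts[[2]]$attached_to <- "none"
  st$mts[[3]]$attached_to <- "L"; st$mts[[4]]$attached_to <- "R"
  sol <- solve_static_positions(st)
  expect_lt(sol$residual, 1e-6)
  expect_equal(sum(sol$F), 0, tolerance = 1e-9)
})

test_that("lattice growth and shrinkage bookkeeping is exact", {
  mt <- microtubule(1, "kMT", "L", minus_pos = -6000, n_sites = 10)
  expect_equal(plus_end(mt), -6000 + 10 * 8)
  ## growth: fires iff u < (rate/d) h, adds an empty site at the plus end
  g <- polymerize_plus_end(mt, rate = 20, h = 1e-3, u = 0.001)
  expect_equal(g$n_sites, 11L)
  expect_equal(plus_end(g), plus_end(mt) + 8)
  expect_equal(g$occupancy[11], 0L)
  expect_equal(polymerize_plus_end(mt, 0, 1e-3, 0)$n_sites, 10L)
  expect_equal(polymerize_plus_end(mt, 20, 1e-3, 0.9)$n_sites, 10L)

  ## right-pole orientation: plus end advances leftward
  mtr <- microtubule(2, "kMT", "R", minus_pos = 6000, n_sites = 10)
  gr <- polymerize_plus_end(mtr, 20, 1e-3, 0.0001)
  expect_equal(plus_end(gr), plus_end(mtr) - 8)

  ## long-run growth speed matches the configured rate (binomial count)
  set.seed(11)
  n <- 1e5; v <- 20; h <- 1e-3; d <- 8
  hits <- sum(runif(n) < v / d * h)
  speed <- hits * d / (n * h)
  se <- d * sqrt((v / d * h) * (1 - v / d * h) * n) / (n * h)
  expect_lt(abs(speed - v), 3 * se)
})

test_that("minus-end depolymerization follows the kinesin-13 rules", {
  mt <- microtubule(1, "kMT", "L", minus_pos = -6000, n_sites = 5)
  ## no motor at the minus end: nothing happens
  s <- depolymerize_minus_end(mt, k_dep = 6, h = 1e-3, u = 0)
  expect_equal(s$n_sites, 5L)

  ## motor at site 1, site 2 empty: shorten by d, motor steps back
  mt$occupancy[1] <- 2L
  s <- depolymerize_minus_end(mt, 6, 1e-3, u = 0.001)
  expect_equal(s$n_sites, 4L)
  expect_equal(s$minus_pos, -6000 + 8)
  expect_equal(s$occupancy[1], 2L)
  expect_false(attr(s, "motor_detached"))

  ## site 2 occupied: the depolymerizing motor is bumped off
  mt$occupancy[2] <- 2L
  s <- depolymerize_minus_end(mt, 6, 1e-3, u = 0.001)
  expect_equal(s$n_sites, 4L)
  expect_equal(s$occupancy[1], 2L)       # the trailing motor moved up
  expect_true(attr(s, "motor_detached"))

  ## event does not fire above threshold
  s <- depolymerize_minus_end(mt, 6, 1e-3, u = 0.9)
  expect_equal(s$n_sites, 5L)
})

test_that("antiparallel overlap is the lattice intersection", {
  ## left bMT spanning [-1000, 200], right spanning [-300, 1000]
  ml <- microtubule(1, "bMT", "L", minus_pos = -1000, n_sites = 120, d = 10)
  mr <- microtubule(2, "bMT", "R", minus_pos = 1000, n_sites = 130, d = 10)
  ov <- overlap_bounds(ml, mr)
  expect_equal(ov$interval, c(-300, 200))
  expect_equal(ov$length, 500)
  expect_lte(ov$length, 10 * min(ml$n_sites, mr$n_sites))
  ## flags only inside the interval
  o <- mt_orientation(ml)
  centers <- ml$minus_pos + o * (seq_len(ml$n_sites) - 0.5) * 10
  expect_equal(ov$left$in_overlap, centers > -300 & centers < 200)

  ## separated plus ends: empty interval, no flags
  mr2 <- microtubule(2, "bMT", "R", minus_pos = 1000, n_sites = 50, d = 10)
  ov2 <- overlap_bounds(ml, mr2)
  expect_equal(ov2$interval, numeric(0))
  expect_equal(ov2$length, 0)
  expect_false(any(ov2$left$in_overlap))
})
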