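#' Specification of a simulation experiment
#'
#' A scenario bundles a preset, parameter overrides, a replicate count with
#' explicit seeds, and (optionally) a one-dimensional sweep grid.
#'
#' @param scenario one of \code{"force_by_configuration"} (fixed
#'   attachments, force and stretch statistics per configuration),
#'   \code{"merotelic_correction"} (type-II merotelic start, default
#'   kinetics), \code{"correction_boundary"} (stability map over the
#'   attachment parameters), \code{"aurora_ablation"} (merotelic start with
#'   the Aurora factor replaced by 1), \code{"flux_sweep"} (merotelic start
#'   over a grid of base polymerization speeds), \code{"oscillation"}
#'   (bi-oriented, detachment disabled), \code{"monotelic_caseI"} and
#'   \code{"monotelic_caseII"} (monotelic start, opposite-pole growth
#'   forbidden/allowed).
#' @param replicates replicate count per grid point (>= 1).
#' @param seeds integer seeds, one per replicate; defaults to
#'   \code{seq_len(replicates)} offset by \code{seed_base}.
#' @param duration_s simulated duration per run (s).
#' @param overrides named list applied to \code{\link{spindle_params}}
#'   arguments.
#' @param sweep named list with one element: the grid, e.g.
#'   \code{list(v_p0 = c(6, 20, 36))}.
#' @param seed_base offset added to the default seeds.
#' @return An object of class \code{"experiment_spec"}.
#' @export
experiment_spec <- function(scenario = c("merotelic_correction",
                                         "force_by_configuration",
                                         "correction_boundary",
                                         "aurora_ablation", "flux_sweep",
                                         "oscillation", "monotelic_caseI",
                                         "monotelic_caseII"),
                            replicates = 1L, seeds = NULL,
                            duration_s = 4000, overrides = list(),
                            sweep = NULL, seed_base = 0L) {
  scenario <- match.arg(scenario)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  if (is.null(seeds)) seeds <- seed_base + seq_len(replicates)
  if (anyDuplicated(seeds)) stop("seeds must be unique")
  if (length(seeds) != replicates) stop("one seed per replicate")
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), length(sweep) == 1L, length(sweep[[1]]) >= 1L)
  }
  structure(list(scenario = scenario, replicates = replicates, seeds = seeds,
                 duration_s = duration_s, overrides = overrides,
                 sweep = sweep),
            class = "experiment_spec")
}

.scenario_setup <- function(scenario, overrides) {
  base <- list()
  preset <- "merotelic2"
  if (scenario == "oscillation") {
    preset <- "bi_oriented"; base$detach_enabled <- FALSE
  } else if (scenario == "aurora_ablation") {
    base$aurora_active <- FALSE
  } else if (scenario == "monotelic_caseI") {
    preset <- "monotelic"; base$case_flag <- "caseI"
  } else if (scenario == "monotelic_caseII") {
    preset <- "monotelic"; base$case_flag <- "caseII"
  } else if (scenario == "force_by_configuration") {
    preset <- "bi_oriented"; base$detach_enabled <- FALSE
  }
  args <- utils::modifyList(base, overrides)
  list(preset = preset, args = args)
}

.build_params <- function(args) {
  poly_keys <- c("v_p0", "B", "F_p0")
  att_keys <- c("k_attach0", "alpha")
  det_keys <- c("b", "A")
  pl <- args[names(args) %in% poly_keys]
  al <- args[names(args) %in% att_keys]
  dl <- args[names(args) %in% det_keys]
  args <- args[!(names(args) %in% c(poly_keys, att_keys, det_keys))]
  if (length(pl)) args$poly <- do.call(polymerization_law, pl)
  if (length(al)) args$attach <- do.call(attachment_law, al)
  if (length(dl)) args$detach <- do.call(detachment_law, dl)
  do.call(spindle_params, args)
}

#' Run an experiment: replicates, sweeps, and aggregate statistics
#'
#' Executes every (grid point, replicate) cell of the specification,
#' collects per-replicate metrics, and aggregates each grid point as mean
#' and standard error (SD/sqrt(n)).  A failed replicate is recorded with
#' its error message, never silently dropped.
#'
#' @param spec an \code{\link{experiment_spec}}.
#' @param preset optional preset override.
#' @param runner the function applied per replicate; replaceable for
#'   testing.  Signature \code{(params, preset, duration_s, seed)}; must
#'   return a \code{\link{simulate_spindle}} result.
#' @return A list with \code{results} (one row per replicate: sweep value,
#'   seed, metrics, error), \code{aggregate} (per grid point: mean and SEM
#'   of each numeric metric, \code{n}), and the resolved \code{spec}.
#' @export
run_experiment <- function(spec, preset = NULL, runner = simulate_spindle) {
  stopifnot(inherits(spec, "experiment_spec"))
  setup <- .scenario_setup(spec$scenario, spec$overrides)
  if (!is.null(preset)) setup$preset <- preset
  sweep_name <- if (is.null(spec$sweep)) NA_character_ else names(spec$sweep)
  grid <- if (is.null(spec$sweep)) NA else spec$sweep[[1]]

  rows <- list()
  for (gi in seq_along(grid)) {
    args <- setup$args
    if (!is.na(sweep_name)) args[[sweep_name]] <- grid[gi]
    params <- .build_params(args)
    for (ri in seq_len(spec$replicates)) {
      seed <- spec$seeds[ri]
      res <- tryCatch({
        sim <- runner(params, setup$preset, duration_s = spec$duration_s,
                      seed = seed)
        m <- spindle_metrics(sim)
        c(list(sweep = grid[gi], seed = seed, error = NA_character_),
          m[c("P_bi", "tau_first_s", "censored", "k_flux_nm_s", "mean_F_pN",
              "mean_dx_nm", "DAP_nm", "period_osc_s", "period_pulse_s",
              "neg_force_freq", "mean_detach_episode_s")])
      }, error = function(e) {
        list(sweep = grid[gi], seed = seed, error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  nm <- unique(unlist(lapply(rows, names)))
  results <- do.call(rbind, lapply(rows, function(r) {
    r <- r[nm]; names(r) <- nm
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
  if (!is.na(sweep_name)) names(results)[names(results) == "sweep"] <- sweep_name

  num_cols <- names(results)[vapply(results, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c(sweep_name, "seed"))
  key <- if (is.na(sweep_name)) rep(1, nrow(results)) else results[[sweep_name]]
  agg <- do.call(rbind, lapply(split(results, key), function(g) {
    ok <- is.na(g$error)
    out <- data.frame(n = sum(ok))
    if (!is.na(sweep_name)) out[[sweep_name]] <- g[[sweep_name]][1]
    for (cc in num_cols) {
      v <- g[[cc]][ok]
      out[[paste0(cc, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(cc, "_sem")]] <- stats::sd(v, na.rm = TRUE) /
        sqrt(max(1, sum(!is.na(v))))
    }
    out
  }))
  rownames(agg) <- NULL
  list(results = results, aggregate = agg, spec = spec,
       preset = setup$preset)
}

#' Stability boundary of the attachment parameters
#'
#' For each attachment-force-sensitivity value \code{alpha}, scans the
#' contact attachment rate grid upward and reports the smallest rate whose
#' merotelic-start run stays stably bi-oriented (post-first-passage
#' bi-orientation probability at or above \code{threshold}).
#'
#' @param alphas attachment sensitivities to scan (1/pN).
#' @param k_attach0_grid ascending grid of contact attachment rates (1/s).
#' @param b Aurora stretch-sensitivity (1/um).
#' @param threshold stability criterion on the bi-orientation probability.
#' @param duration_s run length per grid cell (s).
#' @param seed seed per cell.
#' @param runner replicate runner, replaceable for testing; signature as in
#'   \code{\link{run_experiment}}.
#' @return data.frame with one row per \code{alpha}: the boundary rate
#'   (\code{NA} if the whole column is unstable, i.e. above the grid) and
#'   the per-cell probabilities as an attribute \code{"map"}.
#' @export
boundary_map <- function(alphas, k_attach0_grid, b = 50, threshold = 0.98,
                         duration_s = 4000, seed = 1,
                         runner = simulate_spindle) {
  stopifnot(all(diff(k_attach0_grid) > 0))
  map <- expand.grid(alpha = alphas, k_attach0 = k_attach0_grid)
  map$P_bi <- NA_real_
  for (i in seq_len(nrow(map))) {
    params <- .build_params(list(
      attach = attachment_law(k_attach0 = map$k_attach0[i],
                              alpha = map$alpha[i]),
      detach = detachment_law(b = b)))
    sim <- runner(params, "merotelic2", duration_s = duration_s, seed = seed)
    map$P_bi[i] <- p_bi(sim)
  }
  map$stable <- !is.na(map$P_bi) & map$P_bi >= threshold
  boundary <- do.call(rbind, lapply(split(map, map$alpha), function(g) {
    g <- g[order(g$k_attach0), ]
    j <- which(g$stable)[1]
    data.frame(alpha = g$alpha[1], b = b,
               k_attach0_boundary = if (is.na(j)) NA_real_ else g$k_attach0[j],
               above_grid = is.na(j))
  }))
  rownames(boundary) <- NULL
  attr(boundary, "map") <- map
  boundary
}

#' Deterministic miniature fixtures
#'
#' \code{"two_state"}: a single attach/detach site with constant rates and
#' its closed-form stationary occupancy \code{k_a / (k_a + k_d)}.
#' \code{"single_kmt"}: a pinned-mechanics single-microtubule spindle run.
#' \code{"frozen_rng"}: a short default run twice under one seed, for
#' bit-exact regression comparison.
#'
#' @param kind fixture kind.
#' @param dir optional directory; when given, the manifest (JSON) and any
#'   tables (CSV) are written there.
#' @param k_a,k_d two-state rates (1/s).
#' @param h time step (s).
#' @param n_steps chain length.
#' @param seed RNG seed.
#' @return The fixture as a list (invisibly writes files when \code{dir}
#'   is given).
#' @export
make_fixture <- function(kind = c("two_state", "single_kmt", "frozen_rng"),
                         dir = NULL, k_a = 36.8, k_d = 0.0834, h = 1e-3,
                         n_steps = 1e5, seed = 1) {
  kind <- match.arg(kind)
  fx <- switch(kind,
    two_state = {
      set.seed(seed)
      occ <- simulate_two_state(k_a, k_d, h, n_steps, start_attached = TRUE)
      list(kind = kind, k_a = k_a, k_d = k_d, h = h, n_steps = n_steps,
           seed = seed, expected_occupancy = k_a / (k_a + k_d),
           simulated_occupancy = mean(occ), chain = occ)
    },
    single_kmt = {
      p <- spindle_params(eg5_enabled = FALSE, kif2a_enabled = FALSE,
                          numa_enabled = FALSE,
                          poly = polymerization_law(v_p0 = 0, B = 2))
      sim <- simulate_spindle(p, "bi_oriented", duration_s = n_steps * h,
                              seed = seed,
                              pin = list(F = 5, x_um = 1, yL = 100, yR = 2000))
      list(kind = kind, seed = seed, sim = sim)
    },
    frozen_rng = {
      p <- spindle_params()
      s1 <- simulate_spindle(p, "merotelic2", duration_s = 30, seed = seed)
      s2 <- simulate_spindle(p, "merotelic2", duration_s = 30, seed = seed)
      list(kind = kind, seed = seed, run1 = s1, run2 = s2,
           identical_events = identical(s1$events, s2$events))
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- fx[!vapply(fx, is.recursive, logical(1))]
    jsonlite::write_json(manifest, file.path(dir, paste0(kind, ".json")),
                         auto_unbox = TRUE, digits = NA)
    if (kind == "two_state")
      utils::write.csv(data.frame(step = seq_along(fx$chain),
                                  attached = as.integer(fx$chain)),
                       file.path(dir, "two_state_chain.csv"),
                       row.names = FALSE)
  }
  invisible(fx)
}

#' Two-state attach/detach chain under the fixed-step Bernoulli rule
#'
#' The reduced oracle fixture: one site that attaches at constant rate
#' \code{k_a} and detaches at constant rate \code{k_d}, advanced with one
#' uniform deviate per step through \code{\link{bernoulli_event}}.
#'
#' @param k_a,k_d attachment/detachment rates (1/s).
#' @param h time step (s).
#' @param n_steps chain length.
#' @param start_attached initial state.
#' @return Logical vector of per-step attachment states.
#' @export
simulate_two_state <- function(k_a, k_d, h = 1e-3, n_steps = 1e5,
                               start_attached = TRUE) {
  u <- stats::runif(n_steps)
  out <- logical(n_steps)
  s <- isTRUE(start_attached)
  pa <- k_a * h; pd <- k_d * h
  stopifnot(pa <= 1, pd <= 1)
  for (i in seq_len(n_steps)) {
    s <- if (s) !(u[i] < pd) else (u[i] < pa)
    out[i] <- s
  }
  out
}
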