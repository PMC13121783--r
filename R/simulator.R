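#' @useDynLib spindleflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats acf rbinom runif sd
NULL

## internal label codes used by the core:
## -1 transient detachment, 0 bi-oriented, 1..k merotelic type-k,
## 10 syntelic, 11 monotelic, 12 nothing engaged yet
.label_name <- function(code) {
  ifelse(code == -1, "detached",
  ifelse(code == 0, "bi_oriented",
  ifelse(code == 10, "syntelic",
  ifelse(code == 11, "monotelic",
  ifelse(code == 12, "unengaged", paste0("merotelic", code))))))
}

#' Initial spindle state for a scenario preset
#'
#' Builds the attachment topology and starting lengths for the study
#' scenarios.  All presets place the sister kinetochores near the spindle
#' centre with the bi-oriented equilibrium stretch; kinetochore-microtubule
#' lengths are set so each attached linker starts near its equilibrium
#' load.  Incorrectly attached microtubules span to the far sister.  For
#' the syntelic and monotelic presets all initially attached microtubules
#' come from the right pole; the opposite-pole microtubules start as
#' zero-length nucleation stubs, growable under \code{case_flag = "caseII"}
#' and frozen under \code{"caseI"}.
#'
#' @param params a \code{\link{spindle_params}}.
#' @param preset one of \code{"bi_oriented"}, \code{"merotelic1"},
#'   \code{"merotelic2"}, \code{"merotelic3"}, \code{"syntelic"},
#'   \code{"monotelic"}.
#' @return A list describing the initial state (one row per microtubule:
#'   role, pole, sites, attachment) plus kinetochore positions; consumed by
#'   \code{\link{simulate_spindle}}.
#' @export
make_initial_state <- function(params,
                               preset = c("bi_oriented", "merotelic1",
                                          "merotelic2", "merotelic3",
                                          "syntelic", "monotelic")) {
  preset <- match.arg(preset)
  N <- params$N
  if (preset == "merotelic3" && N < 3L)
    stop("the type-III merotelic preset needs N >= 3")
  d <- params$d_nm
  S <- params$spindle_length_um * 1000
  poleL <- -S / 2; poleR <- S / 2
  x0 <- params$x0_um * 1000
  keff <- params$kappa2 * params$kappa3 / (params$kappa2 + params$kappa3)
  Feq <- params$poly$F_p0 * (params$poly$B - 1)   # equilibrium plus-end load
  stretch <- N * Feq / params$kappa1              # kappa1 balance
  xL <- -(x0 + stretch) / 2; xR <- (x0 + stretch) / 2

  ## lengths that put an attached linker at force Feq given a target sister
  len_for <- function(pole, sister) {
    target <- if (sister == "L") xL else xR
    p <- if (pole == "L") poleL else poleR
    o <- if (pole == "L") 1 else -1
    o * (target - p) - Feq / keff
  }

  n_kmt <- 2L * N
  pole <- c(rep("L", N), rep("R", N))             # kMTs: left pole first
  att <- rep("none", n_kmt)
  correct <- ifelse(pole == "L", "L", "R")

  if (preset == "bi_oriented") {
    att <- correct
  } else if (preset == "merotelic1") {
    att <- correct; att[1] <- "R"
  } else if (preset == "merotelic2") {
    att <- correct; att[1] <- "R"; att[N + 1] <- "L"
  } else if (preset == "merotelic3") {
    att <- correct; att[1] <- "R"; att[2] <- "R"; att[N + 1] <- "L"
  } else if (preset == "syntelic") {
    att[N + 1] <- "L"; att[N + 2] <- "R"
  } else if (preset == "monotelic") {
    att[N + 1] <- "R"; att[N + 2] <- "R"
  }

  n_sites <- integer(n_kmt)
  for (i in seq_len(n_kmt)) {
    if (att[i] != "none") {
      n_sites[i] <- as.integer(round(len_for(pole[i], att[i]) / d))
    } else if (preset %in% c("syntelic", "monotelic") && pole[i] == "L") {
      n_sites[i] <- 0L                            # opposite-pole stubs
    } else {
      n_sites[i] <- as.integer(round(len_for(pole[i], correct[i]) / d))
    }
  }
  growable <- rep(TRUE, n_kmt)
  if (params$case_flag == "caseI" && preset %in% c("syntelic", "monotelic"))
    growable[pole == "L" & att == "none" & n_sites == 0L] <- FALSE

  ## bridging MTs: pairs of antiparallel lattices overlapping near centre
  bmt_len <- as.integer(round((S / 2 + 250) / d))
  role <- c(rep(0L, n_kmt), rep(1L, 2L * N))
  pole_i <- c(ifelse(pole == "L", 0L, 1L), rep(c(0L, 1L), N))
  n_all <- c(n_sites, rep(bmt_len, 2L * N))
  att_i <- c(match(att, c("none", "L", "R")) - 1L, rep(0L, 2L * N))

  list(preset = preset,
       role = role, pole = pole_i, n_sites = n_all, attached = att_i,
       growable = c(growable, rep(TRUE, 2L * N)),
       ever_attached = c(att != "none", rep(FALSE, 2L * N)),
       xL = xL, xR = xR)
}

.core_params <- function(params, pin = NULL) {
  p <- unclass(params)
  p$detach <- unclass(p$detach); p$attach <- unclass(p$attach)
  p$poly <- unclass(p$poly); p$eg5 <- unclass(p$eg5)
  p$kif2a <- unclass(p$kif2a); p$numa <- unclass(p$numa)
  if (is.null(pin)) {
    p$pin <- FALSE; p$pin_F <- 0; p$pin_x_nm <- 0; p$pin_yL <- Inf; p$pin_yR <- Inf
  } else {
    p$pin <- TRUE
    p$pin_F <- pin$F; p$pin_x_nm <- pin$x_um * 1000
    p$pin_yL <- pin$yL; p$pin_yR <- if (is.null(pin$yR)) Inf else pin$yR
  }
  p
}

#' Run the spindle Monte Carlo simulation
#'
#' Advances the full model — quasi-static force balance, motor agents,
#' lattice polymerization/depolymerization, and kinetochore-microtubule
#' detachment/reattachment — for \code{duration_s} simulated seconds in
#' fixed steps of \code{params$h}, sampling the trajectory at
#' \code{sample_every_s} intervals and logging every attachment-state
#' transition and every detachment/reattachment event at tick resolution.
#' The run is a deterministic function of (\code{params}, \code{preset},
#' \code{seed}).
#'
#' @param params a \code{\link{spindle_params}}.
#' @param preset scenario preset name (see \code{\link{make_initial_state}})
#'   or a state list returned by it.
#' @param duration_s simulated duration (s).
#' @param seed integer RNG seed.
#' @param sample_every_s sampling interval for the trajectory (s).
#' @param pin internal fixture hook: a list \code{(F, x_um, yL, yR)} that
#'   freezes the mechanical state (constant force, stretch and reattachment
#'   distances), used by the reduced test fixtures.
#' @return An object of class \code{"spindle_sim"}: \code{trajectory}
#'   (data.frame of 1-s samples), \code{transitions} (attachment-state
#'   changes at tick resolution), \code{events} (detach/attach events),
#'   \code{final}, diagnostic counters, and the call's parameters.
#' @examples
#' \donttest{
#' p <- spindle_params()
#' sim <- simulate_spindle(p, "merotelic2", duration_s = 600, seed = 1)
#' summary(sim)
#' }
#' @export
simulate_spindle <- function(params, preset = "bi_oriented",
                             duration_s = 1000, seed = 1,
                             sample_every_s = 1, pin = NULL) {
  stopifnot(inherits(params, "spindle_params"), duration_s >= 0)
  state <- if (is.character(preset)) make_initial_state(params, preset)
           else preset
  set.seed(as.integer(seed))
  out <- .sim_core(.core_params(params, pin), state, duration_s,
                   sample_every_s)

  N <- params$N; n_kmt <- 2L * N; n_mt <- 4L * N
  tr <- out$traj
  cn <- c("t_s", "xL_nm", "xR_nm",
          paste0("F_pN_k", seq_len(n_kmt)),
          paste0("len_nm_mt", seq_len(n_mt)),
          paste0("att_k", seq_len(n_kmt)),
          "label",
          paste0("removed_mt", seq_len(n_mt)))
  colnames(tr) <- cn
  trajectory <- as.data.frame(tr)
  trajectory$x_minus_x0_nm <- trajectory$xR_nm - trajectory$xL_nm -
    params$x0_um * 1000

  transitions <- data.frame(t_s = out$trans_t, label = out$trans_label,
                            state = .label_name(out$trans_label))
  events <- data.frame(t_s = out$ev_t, mt = out$ev_mt,
                       type = ifelse(out$ev_type == 0, "detach", "attach"),
                       kinetochore = c("none", "L", "R")[out$ev_target + 1L])

  structure(list(trajectory = trajectory, transitions = transitions,
                 events = events,
                 final = list(n_sites = out$final_n_sites,
                              attached = out$final_attached,
                              xL = out$final_xL, xR = out$final_xR),
                 removed = out$removed, arrivals = out$arrivals,
                 motors_bound = out$motors_bound,
                 params = params, preset = state$preset,
                 duration_s = duration_s, seed = seed,
                 sample_every_s = sample_every_s),
            class = "spindle_sim")
}

#' @export
print.spindle_sim <- function(x, ...) {
  cat(sprintf("Spindle simulation: preset '%s', %g s, seed %d\n",
              x$preset %||% "custom", x$duration_s, x$seed))
  cat(sprintf("  %d trajectory samples, %d state transitions, %d attachment events\n",
              nrow(x$trajectory), nrow(x$transitions), nrow(x$events)))
  cat(sprintf("  final state: %s\n",
              .label_name(utils::tail(x$transitions$label, 1))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.spindle_sim <- function(object, burn_in_s = 60, ...) {
  m <- spindle_metrics(object, burn_in_s = burn_in_s)
  cat(sprintf("Spindle simulation summary ('%s', %g s, seed %d)\n",
              object$preset %||% "custom", object$duration_s, object$seed))
  cat(sprintf("  P_bi                 %s\n", format(m$P_bi, digits = 4)))
  cat(sprintf("  first passage to BI  %s s%s\n",
              format(m$tau_first_s, digits = 4),
              if (isTRUE(m$censored)) " (censored)" else ""))
  cat(sprintf("  kMT flux             %.2f nm/s\n", m$k_flux_nm_s))
  cat(sprintf("  mean kMT force       %.2f pN\n", m$mean_F_pN))
  cat(sprintf("  mean x - x0          %.1f nm\n", m$mean_dx_nm))
  cat(sprintf("  DAP                  %.1f +/- %.1f nm\n", m$DAP_nm, m$DAP_sd_nm))
  invisible(m)
}

#' @export
plot.spindle_sim <- function(x, which = c("positions", "label", "forces",
                                          "lengths"), ...) {
  which <- match.arg(which)
  tr <- x$trajectory
  if (which == "positions") {
    graphics::plot(tr$t_s / 60, tr$xL_nm, type = "l", col = "black",
                   xlab = "time (min)", ylab = "position (nm)",
                   ylim = range(c(tr$xL_nm, tr$xR_nm)), ...)
    graphics::lines(tr$t_s / 60, tr$xR_nm, col = "red")
    graphics::legend("topright", c("left kinetochore", "right kinetochore"),
                     col = c("black", "red"), lty = 1, bty = "n")
  } else if (which == "label") {
    graphics::plot(x$transitions$t_s / 60, x$transitions$label, type = "s",
                   xlab = "time (min)", ylab = "attachment-state code", ...)
  } else if (which == "forces") {
    fc <- grep("^F_pN_k", names(tr))
    graphics::matplot(tr$t_s / 60, tr[, fc], type = "l", lty = 1,
                      xlab = "time (min)", ylab = "plus-end force (pN)", ...)
  } else {
    lc <- grep("^len_nm_mt", names(tr))
    graphics::matplot(tr$t_s / 60, tr[, lc] / 1000, type = "l", lty = 1,
                      xlab = "time (min)", ylab = "length (um)", ...)
  }
  invisible(x)
}
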