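#' Full parameter set of the spindle simulation
#'
#' Collects every model constant: geometry, spring network, detachment and
#' attachment laws, plus-end polymerization law, and the three motor
#' species.  The sister-linker stiffness is tied to the ensemble count,
#' \code{kappa1 = N * kappa}, so that the oscillation and pulsation periods
#' do not change with \code{N}.
#'
#' @param N ensemble count (>= 2): the spindle holds \code{2N} kinetochore
#'   microtubules and \code{N} antiparallel bridging-microtubule pairs.
#' @param h Monte Carlo time step (s).
#' @param aurora_active logical; \code{FALSE} replaces the Aurora factor by
#'   1 exactly (kinase ablation).
#' @param case_flag \code{"normal"}, \code{"caseI"} (opposite-pole
#'   kinetochore microtubules cannot grow; treated cell) or \code{"caseII"}
#'   (they start at zero length and may grow; untreated cell).  Only the
#'   syntelic/monotelic presets read it.
#' @param spindle_length_um fixed pole-to-pole distance (um).
#' @param d_nm tubulin site size (nm).
#' @param kappa per-ensemble sister-linker stiffness (pN/nm);
#'   \code{kappa1 = N * kappa}.
#' @param kappa2 kinetochore-microtubule linker stiffness (pN/nm).
#' @param kappa3 minus-end pole anchor stiffness (pN/nm).
#' @param x0_um rest interkinetochore distance (um).
#' @param detach a \code{\link{detachment_law}}.
#' @param attach an \code{\link{attachment_law}}.
#' @param poly a \code{\link{polymerization_law}}.
#' @param eg5 an \code{\link{eg5_params}}.
#' @param kif2a a \code{\link{kif2a_params}}.
#' @param numa a \code{\link{numa_params}}.
#' @param detach_enabled logical; \code{FALSE} freezes all attachments (used
#'   for force/oscillation statistics of fixed attachment configurations).
#' @param eg5_enabled,kif2a_enabled,numa_enabled motor species switches.
#' @param bmt_wall_nm bridging-microtubule plus ends pause within this
#'   margin of the opposite pole.
#' @return An object of class \code{"spindle_params"}.
#' @export
spindle_params <- function(N = 2L, h = 1e-3, aurora_active = TRUE,
                           case_flag = c("normal", "caseI", "caseII"),
                           spindle_length_um = 12, d_nm = 8,
                           kappa = 0.01, kappa2 = 0.1, kappa3 = 0.1,
                           x0_um = 0.5,
                           detach = NULL, attach = NULL, poly = NULL,
                           eg5 = eg5_params(), kif2a = kif2a_params(),
                           numa = numa_params(),
                           detach_enabled = TRUE, eg5_enabled = TRUE,
                           kif2a_enabled = TRUE, numa_enabled = TRUE,
                           bmt_wall_nm = 200) {
  case_flag <- match.arg(case_flag)
  N <- as.integer(N)
  if (N < 2L) stop("N must be at least 2")
  stopifnot(h > 0, spindle_length_um > 0, d_nm > 0, kappa > 0, kappa2 > 0,
            kappa3 > 0, x0_um > 0)
  if (is.null(detach))
    detach <- detachment_law(x0 = x0_um, aurora_active = aurora_active)
  detach$aurora_active <- isTRUE(aurora_active)
  detach$x0 <- x0_um
  if (is.null(attach)) attach <- attachment_law(kappa2 = kappa2)
  attach$kappa2 <- kappa2
  if (is.null(poly)) poly <- polymerization_law()
  ## static-rate time-step guard (dynamic force-dependent rates are handled
  ## in the stepping core)
  ## force- and distance-dependent rates (detachment, reattachment) are
  ## probability-capped in the stepping core; the fixed rates are guarded here
  static <- c(eg5$koff0, eg5$kF0, eg5$mu,
              kif2a$kdiff, kif2a$koff, kif2a$kdep,
              numa$mu, numa$koff)
  if (any(static * h > 0.5))
    stop("a configured rate times the time step exceeds 0.5; refine h")
  structure(list(N = N, h = h, aurora_active = isTRUE(aurora_active),
                 case_flag = case_flag,
                 spindle_length_um = spindle_length_um, d_nm = d_nm,
                 kappa = kappa, kappa1 = N * kappa, kappa2 = kappa2,
                 kappa3 = kappa3, x0_um = x0_um,
                 detach = detach, attach = attach, poly = poly,
                 eg5 = eg5, kif2a = kif2a, numa = numa,
                 detach_enabled = isTRUE(detach_enabled),
                 eg5_enabled = isTRUE(eg5_enabled),
                 kif2a_enabled = isTRUE(kif2a_enabled),
                 numa_enabled = isTRUE(numa_enabled),
                 bmt_wall_nm = bmt_wall_nm),
            class = "spindle_params")
}

#' @export
print.spindle_params <- function(x, ...) {
  cat("Spindle simulation parameters\n")
  cat(sprintf("  N = %d ensembles (%d kMTs, %d bMTs), h = %g s\n",
              x$N, 2 * x$N, 2 * x$N, x$h))
  cat(sprintf("  spindle length %g um, d = %g nm, x0 = %g um\n",
              x$spindle_length_um, x$d_nm, x$x0_um))
  cat(sprintf("  kappa1 = %g, kappa2 = %g, kappa3 = %g pN/nm\n",
              x$kappa1, x$kappa2, x$kappa3))
  cat(sprintf("  Aurora %s (A = %g, b = %g /um); attachment k0 = %g /s, alpha = %g /pN\n",
              if (x$aurora_active) "active" else "ablated",
              x$detach$A, x$detach$b, x$attach$k_attach0, x$attach$alpha))
  cat(sprintf("  v_p0 = %g nm/s, B = %g, F_p0 = %g pN; case %s\n",
              x$poly$v_p0, x$poly$B, x$poly$F_p0, x$case_flag))
  invisible(x)
}
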