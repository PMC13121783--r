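#' Classify an attachment configuration
#'
#' Labels an attachment state: \code{bi_oriented} (no incorrect
#' attachment), \code{merotelic<k>} (k incorrect attachments, both poles
#' engaged across the pair), \code{syntelic} (both sisters attached, all
#' attached microtubules from one pole), \code{monotelic} (exactly one
#' sister attached, all from one pole), or \code{detached} whenever any
#' considered microtubule is unattached (transient detachment).  An
#' attachment is incorrect iff the microtubule binds the sister facing away
#' from its pole of origin.  Microtubules that have never engaged a
#' kinetochore (zero-length nucleation stubs of the monotelic/syntelic
#' scenarios) are excluded until their first attachment.
#'
#' Precedence follows the mutually exclusive taxonomy: monotelic, then
#' syntelic, then incorrect-count.
#'
#' @param pole character vector, \code{"L"}/\code{"R"}: pole of origin per
#'   kinetochore microtubule.
#' @param attached character vector, \code{"none"}/\code{"L"}/\code{"R"}.
#' @param ever_attached logical; microtubules never yet attached are not
#'   considered.  Defaults to considering every microtubule.
#' @return A one-row data.frame: \code{state}, \code{code} (the trace
#'   coding: 0 bi-oriented, k merotelic-k, -1 detached, 10 syntelic, 11
#'   monotelic, 12 nothing engaged), \code{incorrect_count}.
#' @export
classify_attachment <- function(pole, attached,
                                ever_attached = rep(TRUE, length(pole))) {
  stopifnot(length(pole) == length(attached),
            all(pole %in% c("L", "R")), all(attached %in% c("none", "L", "R")))
  keep <- ever_attached
  pole <- pole[keep]; attached <- attached[keep]
  out <- function(code, k) data.frame(state = .label_name(code), code = code,
                                      incorrect_count = k)
  if (length(pole) == 0L) return(out(12L, 0L))
  if (any(attached == "none")) return(out(-1L, NA_integer_))
  incorrect <- sum(pole != attached)
  sisters <- unique(attached)
  poles <- unique(pole)
  if (length(sisters) == 1L && length(poles) == 1L) return(out(11L, incorrect))
  if (length(sisters) == 2L && length(poles) == 1L) return(out(10L, incorrect))
  if (incorrect == 0L) return(out(0L, 0L))
  out(incorrect, incorrect)
}

.erroneous_codes <- c(1:9, 10, 11)

.label_durations <- function(sim) {
  tr <- sim$transitions
  t_end <- sim$duration_s
  data.frame(t0 = tr$t_s, t1 = c(tr$t_s[-1], t_end), label = tr$label)
}

#' Bi-orientation probability after first bi-orientation
#'
#' Fraction of time spent bi-oriented among the time spent in the
#' bi-oriented plus all erroneous states, measured from the first entry
#' into the bi-oriented state onward.  Transient-detachment intervals are
#' excluded from both numerator and denominator (the detached microtubule
#' reattaches within tens of milliseconds).
#'
#' @param sim a \code{\link{simulate_spindle}} result.
#' @param t_start optional start time (s); defaults to the first entry into
#'   bi-orientation.
#' @return Probability in [0, 1], or \code{NA} if the trajectory never
#'   reaches bi-orientation.
#' @export
p_bi <- function(sim, t_start = NULL) {
  if (is.null(t_start)) {
    fp <- first_passage_to_bi(sim)
    if (is.na(fp$t_s) || fp$censored) return(NA_real_)
    t_start <- fp$t_s
  }
  dur <- .label_durations(sim)
  dur$t0 <- pmax(dur$t0, t_start)
  dur <- dur[dur$t1 > dur$t0, , drop = FALSE]
  w <- dur$t1 - dur$t0
  t_bi <- sum(w[dur$label == 0])
  t_err <- sum(w[dur$label %in% .erroneous_codes])
  if (t_bi + t_err <= 0) return(NA_real_)
  t_bi / (t_bi + t_err)
}

#' Sample-based bi-orientation probability (independent recomputation)
#'
#' Same definition as \code{\link{p_bi}} but computed from the 1-s sampled
#' labels instead of the exact transition log; used as a cross-check.
#' @inheritParams p_bi
#' @export
p_bi_samples <- function(sim, t_start = NULL) {
  lab <- sim$trajectory$label
  t <- sim$trajectory$t_s
  if (is.null(t_start)) {
    i0 <- which(lab == 0)[1]
    if (is.na(i0)) return(NA_real_)
    t_start <- t[i0]
  }
  lab <- lab[t >= t_start]
  n_bi <- sum(lab == 0); n_err <- sum(lab %in% .erroneous_codes)
  if (n_bi + n_err == 0) return(NA_real_)
  n_bi / (n_bi + n_err)
}

#' First passage to the bi-oriented state
#'
#' @inheritParams p_bi
#' @return A list: \code{t_s} (time of first bi-orientation, 0 if the run
#'   starts bi-oriented, \code{NA} if never reached) and \code{censored}.
#' @export
first_passage_to_bi <- function(sim) {
  tr <- sim$transitions
  i <- which(tr$label == 0)[1]
  if (is.na(i)) list(t_s = NA_real_, censored = TRUE)
  else list(t_s = tr$t_s[i], censored = FALSE)
}

#' Durations of transient kMT-detachment episodes
#'
#' Every maximal interval spent in the transient-detachment state, with the
#' state it resolved into.
#'
#' @inheritParams p_bi
#' @param after_first_bi restrict to episodes after the first entry into
#'   bi-orientation.
#' @return data.frame with \code{t0}, \code{duration_s}, \code{next_label}
#'   (\code{NA} for an episode cut off by the end of the run).
#' @export
detachment_episodes <- function(sim, after_first_bi = TRUE) {
  tr <- sim$transitions
  idx <- which(tr$label == -1)
  if (after_first_bi) {
    fp <- first_passage_to_bi(sim)
    idx <- if (is.na(fp$t_s)) integer(0) else idx[tr$t_s[idx] >= fp$t_s]
  }
  if (length(idx) == 0L)
    return(data.frame(t0 = numeric(0), duration_s = numeric(0),
                      next_label = integer(0)))
  t1 <- ifelse(idx < nrow(tr), tr$t_s[idx + 1], sim$duration_s)
  nl <- ifelse(idx < nrow(tr), tr$label[idx + 1], NA_integer_)
  data.frame(t0 = tr$t_s[idx], duration_s = t1 - tr$t_s[idx],
             next_label = as.integer(nl))
}

#' Poleward flux rate of the kinetochore microtubules
#'
#' Mean poleward lattice speed, measured as tubulins removed at the minus
#' ends per unit time times the site size, averaged over the kinetochore
#' microtubules and a stationary window.
#'
#' @inheritParams p_bi
#' @param t_start,t_end window bounds (s); the window must cover at least
#'   60 s.  \code{t_end = NULL} uses the end of the run.
#' @return Flux in nm/s.
#' @export
flux_rate <- function(sim, t_start = 600, t_end = NULL) {
  tr <- sim$trajectory
  if (is.null(t_end)) t_end <- max(tr$t_s)
  if (t_end - t_start < 60) stop("flux window must cover at least 60 s")
  n_kmt <- 2L * sim$params$N
  cols <- paste0("removed_mt", seq_len(n_kmt))
  i0 <- which.min(abs(tr$t_s - t_start)); i1 <- which.min(abs(tr$t_s - t_end))
  d <- sim$params$d_nm
  mean(as.numeric(tr[i1, cols] - tr[i0, cols])) * d / (tr$t_s[i1] - tr$t_s[i0])
}

#' Deviation from the average position (oscillation amplitude proxy)
#'
#' Mean absolute deviation of the kinetochore-pair centre from the spindle
#' centre, plus its standard deviation.
#'
#' @inheritParams flux_rate
#' @return List with \code{DAP_nm} and \code{DAP_sd_nm}.
#' @export
dap <- function(sim, t_start = 60) {
  tr <- sim$trajectory
  keep <- tr$t_s >= t_start
  dev <- abs((tr$xL_nm[keep] + tr$xR_nm[keep]) / 2)
  list(DAP_nm = mean(dev), DAP_sd_nm = stats::sd(dev))
}

#' Dominant period of a sampled series by autocorrelation
#'
#' Linearly detrends the series, computes its autocorrelation, and locates
#' the first local maximum after the autocorrelation's first zero crossing
#' (a lightly smoothed copy is used for the peak search).  The estimate is
#' then sharpened by locating the autocorrelation maxima near the first few
#' integer multiples of that lag, refining each by parabolic interpolation,
#' and averaging the implied periods.
#'
#' @param x numeric series sampled at interval \code{dt}.
#' @param dt sampling interval (s).
#' @return Period in seconds, or \code{NA} if no peak is found.
#' @export
estimate_period <- function(x, dt = 1) {
  n <- length(x)
  if (n < 16 || stats::sd(x) == 0) return(NA_real_)
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ tt))
  r <- as.numeric(stats::acf(x, lag.max = n - 2, plot = FALSE,
                             demean = TRUE)$acf)
  w <- as.numeric(stats::filter(r, rep(1 / 9, 9), sides = 2))
  w[is.na(w)] <- r[is.na(w)]
  zc <- which(w[-1] < 0)[1]
  if (is.na(zc)) return(NA_real_)
  T0 <- NA_real_
  for (k in (zc + 2):(length(w) - 1)) {
    if (w[k] >= w[k - 1] && w[k] > w[k + 1] && w[k] > 0) { T0 <- k - 1; break }
  }
  if (is.na(T0) || T0 < 2) return(NA_real_)
  M <- min(4, floor((length(r) - 2) / T0))
  periods <- numeric(0)
  for (m in seq_len(max(1, M))) {
    ctr <- m * T0
    lo <- max(2, round(ctr - 0.25 * T0)); hi <- min(length(r) - 1,
                                                    round(ctr + 0.25 * T0))
    if (hi <= lo) next
    i <- lo - 1 + which.max(r[lo:hi])
    lag <- i - 1
    denom <- r[i - 1] - 2 * r[i] + r[i + 1]
    if (is.finite(denom) && abs(denom) > .Machine$double.eps)
      lag <- lag + 0.5 * (r[i - 1] - r[i + 1]) / denom
    periods <- c(periods, lag / m)
  }
  if (!length(periods)) return(T0 * dt)
  mean(periods) * dt
}

#' Oscillation and pulsation periods of a trajectory
#'
#' The slow kinetochore oscillation is read from the kinetochore-centre
#' trace and the pulsation (interkinetochore-distance cycle) from the
#' \code{x - x0} trace, both by \code{\link{estimate_period}}.
#'
#' @inheritParams flux_rate
#' @return List with \code{period_osc_s} and \code{period_pulse_s}.
#' @export
periods <- function(sim, t_start = 120) {
  tr <- sim$trajectory
  keep <- tr$t_s >= t_start
  dt <- sim$sample_every_s
  center <- (tr$xL_nm[keep] + tr$xR_nm[keep]) / 2
  dx <- tr$x_minus_x0_nm[keep]
  list(period_osc_s = estimate_period(center, dt),
       period_pulse_s = estimate_period(dx, dt))
}

#' Plus-end force statistics
#'
#' Mean signed plus-end force over attached kinetochore microtubules and
#' samples (pulling positive), a binned histogram, and the frequency of
#' negative (pushing) forces.
#'
#' @inheritParams flux_rate
#' @param breaks passed to \code{\link[graphics]{hist}} breaks.
#' @return List with \code{mean_F_pN}, \code{neg_force_freq},
#'   \code{histogram} (counts and breaks).
#' @export
force_stats <- function(sim, t_start = 60, breaks = seq(-20, 40, by = 1)) {
  tr <- sim$trajectory
  keep <- tr$t_s >= t_start
  n_kmt <- 2L * sim$params$N
  Fm <- as.matrix(tr[keep, paste0("F_pN_k", seq_len(n_kmt)), drop = FALSE])
  Am <- as.matrix(tr[keep, paste0("att_k", seq_len(n_kmt)), drop = FALSE])
  f <- Fm[Am > 0]
  if (length(f) == 0) return(list(mean_F_pN = NA_real_,
                                  neg_force_freq = NA_real_,
                                  histogram = NULL))
  br <- range(c(breaks, f)); br <- seq(floor(br[1]), ceiling(br[2]), by = 1)
  h <- graphics::hist(f, breaks = br, plot = FALSE)
  list(mean_F_pN = mean(f), neg_force_freq = mean(f < 0),
       histogram = list(mids = h$mids, counts = h$counts))
}

#' Summary metrics of a simulation
#'
#' @inheritParams p_bi
#' @param burn_in_s transient discarded for the stationary statistics (s).
#' @return A list with the standard summaries: \code{P_bi},
#'   \code{tau_first_s}, \code{censored}, \code{k_flux_nm_s},
#'   \code{mean_F_pN}, \code{mean_dx_nm}, \code{DAP_nm}, \code{DAP_sd_nm},
#'   \code{period_osc_s}, \code{period_pulse_s}, \code{neg_force_freq},
#'   \code{mean_detach_episode_s}, \code{n_detach_episodes}.
#' @export
spindle_metrics <- function(sim, burn_in_s = 60) {
  fp <- first_passage_to_bi(sim)
  fs <- force_stats(sim, t_start = burn_in_s)
  dp <- dap(sim, t_start = burn_in_s)
  pr <- periods(sim, t_start = max(burn_in_s, 120))
  tr <- sim$trajectory
  keep <- tr$t_s >= burn_in_s
  flux <- tryCatch(flux_rate(sim, t_start = min(burn_in_s, 600)),
                   error = function(e) NA_real_)
  ep <- detachment_episodes(sim)
  ep_bi <- ep[!is.na(ep$next_label) & ep$next_label == 0, , drop = FALSE]
  list(P_bi = p_bi(sim), tau_first_s = fp$t_s, censored = fp$censored,
       k_flux_nm_s = flux,
       mean_F_pN = fs$mean_F_pN,
       mean_dx_nm = mean(tr$x_minus_x0_nm[keep]),
       DAP_nm = dp$DAP_nm, DAP_sd_nm = dp$DAP_sd_nm,
       period_osc_s = pr$period_osc_s, period_pulse_s = pr$period_pulse_s,
       neg_force_freq = fs$neg_force_freq,
       mean_detach_episode_s = if (nrow(ep_bi)) mean(ep_bi$duration_s) else NA_real_,
       n_detach_episodes = nrow(ep))
}
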