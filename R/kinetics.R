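#' Catch-slip detachment law for kinetochore-microtubule attachments
#'
#' Bundles the constants of the phenomenological force-dependent detachment
#' rate together with the Aurora-B tension-sensing term.  The attachment
#' lifetime first rises with pulling force (catch branch) and then falls
#' (slip branch), with a maximum near 5 pN.  Aurora B multiplies the
#' detachment rate by \code{X_detach = 1 + A * exp(-b * (x - x0))}, largest
#' when the interkinetochore stretch \code{x - x0} is small (low tension).
#'
#' @param k1,k2 catch/slip rate constants (1/min).
#' @param F1,F2 force scales of the catch and slip exponentials (pN).
#' @param A dimensionless Aurora amplitude; \code{1 + A} is the fold increase
#'   of the detachment rate at zero stretch.
#' @param b Aurora sensitivity to interkinetochore stretch (1/um).
#' @param x0 rest (zero-force) interkinetochore distance (um).
#' @param aurora_active logical; if \code{FALSE} the Aurora factor is
#'   identically 1 (kinase-ablation construction).
#' @return An object of class \code{"detachment_law"}.
#' @examples
#' law <- detachment_law()
#' attachment_lifetime(0, law)    # 1/k2, about 13 min
#' attachment_lifetime(5, law)    # near the catch-slip maximum, about 50 min
#' @export
detachment_law <- function(k1 = 6.6e-4, k2 = 7.7e-2, F1 = 1.07, F2 = 1.86,
                           A = 64, b = 50, x0 = 0.5, aurora_active = TRUE) {
  stopifnot(is.finite(k1), is.finite(k2), is.finite(F1), is.finite(F2),
            is.finite(A), is.finite(b), is.finite(x0))
  if (k1 <= 0 || k2 <= 0 || F1 <= 0 || F2 <= 0)
    stop("rate and force constants of the detachment law must be positive")
  if (A < 0 || b < 0 || x0 <= 0)
    stop("require A >= 0, b >= 0, x0 > 0")
  structure(list(k1 = k1, k2 = k2, F1 = F1, F2 = F2, A = A, b = b, x0 = x0,
                 aurora_active = isTRUE(aurora_active)),
            class = "detachment_law")
}

#' Distance-dependent attachment law
#'
#' Rate at which a detached kinetochore microtubule reattaches to a
#' kinetochore a distance \code{y} away:
#' \code{k_attach(y) = k_attach0 * exp(-alpha * kappa2 * |y|)}.
#'
#' @param k_attach0 attachment rate at contact (1/s).
#' @param alpha force sensitivity of attachment (1/pN).
#' @param kappa2 stiffness of the kinetochore-microtubule linker (pN/nm).
#' @return An object of class \code{"attachment_law"}.
#' @export
attachment_law <- function(k_attach0 = 100, alpha = 0.05, kappa2 = 0.1) {
  stopifnot(is.finite(k_attach0), is.finite(alpha), is.finite(kappa2))
  if (k_attach0 <= 0 || alpha < 0 || kappa2 <= 0)
    stop("require k_attach0 > 0, alpha >= 0, kappa2 > 0")
  structure(list(k_attach0 = k_attach0, alpha = alpha, kappa2 = kappa2),
            class = "attachment_law")
}

#' Attachment lifetime under a pulling force
#'
#' Lifetime of a kinetochore-microtubule attachment under constant pulling
#' force \code{F}, the inverse of the catch-slip detachment rate.  Negative
#' (pushing) forces are clamped to zero: the law was fit to pulling-force
#' data only and the catch branch must not be extrapolated to compression.
#'
#' @param F pulling force on the microtubule plus end (pN); vectorised.
#' @param law a \code{\link{detachment_law}}.
#' @return Lifetime in minutes.
#' @export
attachment_lifetime <- function(F, law = detachment_law()) {
  if (!inherits(law, "detachment_law")) stop("`law` must be a detachment_law")
  if (any(!is.finite(F))) stop("non-finite force")
  F <- pmax(F, 0)
  rate <- law$k1 * exp(F / law$F2) * (1 - exp(-F / law$F1)) +
          law$k2 * exp(F / law$F2) * exp(-F / law$F1)
  1 / rate
}

#' Detachment rate with optional Aurora-B modulation
#'
#' Instantaneous detachment rate of an attached kinetochore microtubule
#' bearing pulling force \code{F} while the sister kinetochores are a
#' distance \code{x} apart.  With Aurora active the base catch-slip rate is
#' multiplied by \code{X_detach(x) = 1 + A * exp(-b * (x - x0))}; with
#' Aurora ablated \code{X_detach = 1} exactly.
#'
#' @param F pulling force (pN); pushing clamped to 0.
#' @param x interkinetochore distance (um), \code{x >= 0}.
#' @param law a \code{\link{detachment_law}}.
#' @return Rate in 1/s (the lifetime law is stated per minute and converted).
#' @export
detach_rate <- function(F, x, law = detachment_law()) {
  if (any(!is.finite(F)) || any(!is.finite(x))) stop("non-finite input")
  if (any(x < 0)) stop("interkinetochore distance must be >= 0")
  base <- 1 / attachment_lifetime(F, law) / 60
  if (law$aurora_active) {
    ## phosphorylation saturates at zero tension: stretch below the rest
    ## separation is clamped, so X_detach stays within [1, 1 + A]
    base * (1 + law$A * exp(-law$b * pmax(x - law$x0, 0)))
  } else {
    base
  }
}

#' Reattachment rate at a plus-end-to-kinetochore distance
#'
#' @param y signed distance from the detached plus end to the kinetochore
#'   (nm); only \code{|y|} enters.
#' @param law an \code{\link{attachment_law}}.
#' @return Rate in 1/s.
#' @export
attach_rate <- function(y, law = attachment_law()) {
  if (!inherits(law, "attachment_law")) stop("`law` must be an attachment_law")
  if (any(!is.finite(y))) stop("non-finite distance")
  law$k_attach0 * exp(-law$alpha * law$kappa2 * abs(y))
}

#' Fixed-step Bernoulli event rule
#'
#' The elementary update of the fixed-step Monte Carlo scheme: an event of
#' rate \code{rate} fires in a step of length \code{h} iff the uniform
#' deviate \code{u} is below \code{rate * h}.  The caller supplies one
#' independent deviate per entity per process per step.
#'
#' @param rate event rate (1/s), \code{rate >= 0}.
#' @param h time step (s).
#' @param u uniform deviate in [0, 1); vectorised over \code{u} and
#'   \code{rate}.
#' @return Logical.
#' @export
bernoulli_event <- function(rate, h, u) {
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rate must be finite and >= 0")
  stopifnot(h > 0)
  p <- rate * h
  if (any(p > 1)) stop("rate * h exceeds 1: probability overflow, refine the time step")
  if (any(p > 0.5)) warning("rate * h exceeds 0.5: first-order Bernoulli approximation is coarse")
  u < p
}
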