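## Geometry, tubulin lattices, and the quasi-static spring network.
## Axis convention: nm coordinates, left pole negative, right pole positive.
## Orientation +1 for left-pole microtubules (plus end points right, toward
## the spindle centre), -1 for right-pole microtubules.  Pulling forces on a
## kMT plus end are positive; pushing (plus end toward minus end) negative.

## occupancy codes shared across the package
OCC_EMPTY <- 0L
OCC_EG5   <- 1L
OCC_KIF2A <- 2L
OCC_NUMA  <- 3L

#' Force-dependent plus-end polymerization law
#'
#' An attached kinetochore microtubule grows at \code{v_p0 / B * (1 + F/F_p0)}:
#' slower than a free plus end at zero force (fewer polymerases fit next to
#' the kinetochore linkers, and kinetochore-localised depolymerases act
#' there), and accelerated by pulling force.  Detached kinetochore
#' microtubules and bridging microtubules grow at the base rate \code{v_p0}.
#'
#' @param v_p0 base plus-end polymerization speed (nm/s).
#' @param B dimensionless slow-down factor at the kinetochore (> 1).
#' @param F_p0 force sensitivity scale (pN).
#' @return An object of class \code{"polymerization_law"}.
#' @export
polymerization_law <- function(v_p0 = 20, B = 1.15, F_p0 = 5 / (B - 1)) {
  stopifnot(is.finite(v_p0), is.finite(B), is.finite(F_p0))
  if (B <= 1) stop("B must exceed 1")
  if (v_p0 < 0 || F_p0 <= 0) stop("require v_p0 >= 0 and F_p0 > 0")
  structure(list(v_p0 = v_p0, B = B, F_p0 = F_p0),
            class = "polymerization_law")
}

#' Plus-end growth speed of a kinetochore microtubule
#'
#' Signed force enters the law: pulling (positive) accelerates growth,
#' pushing (negative) slows it, and growth stalls at \code{F = -F_p0}
#' (the speed is floored at zero, never negative — plus-end
#' depolymerization is not part of the model).
#'
#' @param F signed plus-end force (pN, pulling positive).
#' @param attached logical; detached plus ends grow at \code{v_p0}.
#' @param law a \code{\link{polymerization_law}}.
#' @return Speed in nm/s.
#' @export
kmt_polymerization_rate <- function(F, attached, law = polymerization_law()) {
  if (any(!is.finite(F))) stop("non-finite force")
  ifelse(attached, pmax(0, law$v_p0 / law$B * (1 + F / law$F_p0)), law$v_p0)
}

#' Discrete microtubule lattice
#'
#' A rigid rod of \code{n_sites} tubulin sites of size \code{d}, anchored at
#' its minus end, with at most one motor per site.
#'
#' @param id integer identifier.
#' @param role \code{"kMT"} or \code{"bMT"}.
#' @param pole \code{"L"} or \code{"R"} (pole of origin; fixes orientation).
#' @param minus_pos axis coordinate of the minus end (nm).
#' @param n_sites number of tubulin sites (>= 0).
#' @param d site size (nm per tubulin).
#' @param attached_to \code{"none"}, \code{"L"} or \code{"R"} (kMT only).
#' @return An object of class \code{"microtubule"}.
#' @export
microtubule <- function(id = 1L, role = c("kMT", "bMT"), pole = c("L", "R"),
                        minus_pos = 0, n_sites = 0L, d = 8,
                        attached_to = "none") {
  role <- match.arg(role); pole <- match.arg(pole)
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 0, d > 0, attached_to %in% c("none", "L", "R"))
  if (role == "bMT" && attached_to != "none")
    stop("bridging microtubules do not attach to kinetochores")
  structure(list(id = as.integer(id), role = role, pole = pole,
                 minus_pos = minus_pos, n_sites = n_sites, d = d,
                 occupancy = rep(OCC_EMPTY, n_sites),
                 in_overlap = rep(FALSE, n_sites),
                 attached_to = attached_to),
            class = "microtubule")
}

#' @rdname microtubule
#' @param mt a \code{microtubule}.
#' @export
mt_orientation <- function(mt) if (mt$pole == "L") 1 else -1

#' @rdname microtubule
#' @export
plus_end <- function(mt) mt$minus_pos + mt_orientation(mt) * mt$n_sites * mt$d

#' Quasi-static positions and forces of the spring network
#'
#' Solves the static balance of the spindle's spring network: each attached
#' kinetochore microtubule acts through the series combination of its
#' plus-end linker (kappa2) and minus-end pole anchor (kappa3), so it is
#' equivalent to a spring of stiffness \code{kappa2*kappa3/(kappa2+kappa3)}
#' anchored at the relaxed plus-end position \code{pole + o * length}; the
#' sister kinetochores are joined by the kappa1 linker with rest length
#' \code{x0}.  Microtubule rods are rigid; springs equilibrate instantly
#' relative to the 1-ms event clock.
#'
#' @param state a list with elements \code{poles} (named numeric,
#'   \code{c(L=, R=)} nm), \code{kappa} (list \code{kappa1, kappa2, kappa3}
#'   in pN/nm), \code{x0_nm}, \code{mts} (list of \code{\link{microtubule}}),
#'   and optionally \code{prev} (list \code{xL, xR} used when no kinetochore
#'   is attached to anything).
#' @return A list: \code{xL}, \code{xR}, \code{x} (separation, nm), per-MT
#'   signed plus-end force \code{F} (pN, pulling positive, 0 when detached),
#'   per-MT \code{minus_pos}, and the largest residual net force
#'   (\code{residual}, pN).
#' @export
solve_static_positions <- function(state) {
  kp <- state$kappa
  keff <- kp$kappa2 * kp$kappa3 / (kp$kappa2 + kp$kappa3)
  x0 <- state$x0_nm
  poles <- state$poles
  mts <- state$mts
  o <- vapply(mts, mt_orientation, numeric(1))
  L <- vapply(mts, function(m) m$n_sites * m$d, numeric(1))
  pole_pos <- poles[vapply(mts, function(m) m$pole, character(1))]
  r <- pole_pos + o * L                       # relaxed plus-end position
  att <- vapply(mts, function(m) m$attached_to, character(1))

  nL <- sum(att == "L"); nR <- sum(att == "R")
  if (nL + nR == 0L) {
    prev <- state$prev
    xL <- if (is.null(prev)) -x0 / 2 else prev$xL
    xR <- if (is.null(prev))  x0 / 2 else prev$xR
  } else {
    SL <- sum(r[att == "L"]); SR <- sum(r[att == "R"])
    A <- rbind(c(keff * nL + kp$kappa1, -kp$kappa1),
               c(-kp$kappa1, keff * nR + kp$kappa1))
    rhs <- c(keff * SL - kp$kappa1 * x0, keff * SR + kp$kappa1 * x0)
    sol <- solve(A, rhs)
    xL <- sol[1]; xR <- sol[2]
  }

  xa <- ifelse(att == "L", xL, ifelse(att == "R", xR, NA_real_))
  F <- ifelse(att == "none", 0, keff * o * (xa - r))
  minus_pos <- ifelse(att == "none", pole_pos,
                      (kp$kappa3 * pole_pos + kp$kappa2 * (xa - o * L)) /
                        (kp$kappa2 + kp$kappa3))

  ## residual check on every free body
  plus <- minus_pos + o * L
  f_mt <- kp$kappa3 * (pole_pos - minus_pos) +
    ifelse(att == "none", 0, kp$kappa2 * (xa - plus))
  fL <- sum(kp$kappa2 * (plus[att == "L"] - xL)) +
    kp$kappa1 * (xR - xL - x0)
  fR <- sum(kp$kappa2 * (plus[att == "R"] - xR)) -
    kp$kappa1 * (xR - xL - x0)
  if (nL + nR == 0L) { fL <- 0; fR <- 0 }
  res <- max(abs(c(f_mt, if (nL > 0 || nR > 0) c(fL, fR))))

  list(xL = unname(xL), xR = unname(xR), x = unname(xR - xL),
       F = unname(F), minus_pos = unname(minus_pos), residual = unname(res))
}

#' Stochastic plus-end polymerization step
#'
#' Adds one tubulin with probability \code{(rate/d) * h}; the plus end then
#' advances by \code{d} toward the spindle centre and the new site is empty.
#'
#' @param mt a \code{\link{microtubule}}.
#' @param rate growth speed (nm/s).
#' @param h time step (s).
#' @param u uniform deviate.
#' @return The updated microtubule.
#' @export
polymerize_plus_end <- function(mt, rate, h, u) {
  stopifnot(rate >= 0)
  if (bernoulli_event(rate / mt$d, h, u)) {
    mt$n_sites <- mt$n_sites + 1L
    mt$occupancy <- c(mt$occupancy, OCC_EMPTY)
    mt$in_overlap <- c(mt$in_overlap, FALSE)
  }
  mt
}

#' Stochastic minus-end depolymerization step
#'
#' A tubulin is removed from the minus end with probability \code{k_dep * h}
#' only while a kinesin-13 occupies the first site.  After removal the
#' resident motor detaches if the old second site was occupied, otherwise it
#' steps back onto the new first site.  The minus end advances by \code{d}
#' toward the centre; a zero-length lattice is left unchanged (the
#' nucleation stub persists at the pole and may regrow).
#'
#' @inheritParams polymerize_plus_end
#' @param k_dep removal rate while a kinesin-13 occupies the minus end (1/s).
#' @return The updated microtubule, with attribute \code{"motor_detached"}
#'   set \code{TRUE} when the depolymerizing motor left the lattice.
#' @export
depolymerize_minus_end <- function(mt, k_dep, h, u) {
  detached <- FALSE
  if (mt$n_sites > 0L && mt$occupancy[1] == OCC_KIF2A &&
      bernoulli_event(k_dep, h, u)) {
    second_occupied <- mt$n_sites > 1L && mt$occupancy[2] != OCC_EMPTY
    mt$occupancy <- mt$occupancy[-1]
    mt$in_overlap <- mt$in_overlap[-1]
    mt$n_sites <- mt$n_sites - 1L
    mt$minus_pos <- mt$minus_pos + mt_orientation(mt) * mt$d
    if (second_occupied) {
      detached <- TRUE              # bumped off by the trailing motor
    } else if (mt$n_sites > 0L) {
      mt$occupancy[1] <- OCC_KIF2A  # backward step onto the new first site
    } else {
      detached <- TRUE              # lattice gone
    }
  }
  attr(mt, "motor_detached") <- detached
  mt
}

#' Antiparallel overlap of a bridging-microtubule pair
#'
#' @param mt_left,mt_right the two antiparallel bridging microtubules of one
#'   ensemble (left-pole and right-pole).
#' @return A list: \code{interval} (numeric \code{c(lo, hi)} nm, or
#'   \code{numeric(0)} when the plus ends have not met), \code{length} (nm),
#'   and the two microtubules with their per-site \code{in_overlap} flags
#'   updated.
#' @export
overlap_bounds <- function(mt_left, mt_right) {
  stopifnot(mt_left$pole == "L", mt_right$pole == "R")
  lo <- max(mt_left$minus_pos, plus_end(mt_right))
  hi <- min(plus_end(mt_left), mt_right$minus_pos)
  empty <- !(hi > lo)
  flag <- function(mt, lo, hi) {
    if (mt$n_sites == 0L) { mt$in_overlap <- logical(0); return(mt) }
    o <- mt_orientation(mt)
    centers <- mt$minus_pos + o * (seq_len(mt$n_sites) - 0.5) * mt$d
    mt$in_overlap <- if (empty) rep(FALSE, mt$n_sites) else
      centers > lo & centers < hi
    mt
  }
  mt_left <- flag(mt_left, lo, hi); mt_right <- flag(mt_right, lo, hi)
  list(interval = if (empty) numeric(0) else c(lo, hi),
       length = if (empty) 0 else hi - lo,
       left = mt_left, right = mt_right)
}
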