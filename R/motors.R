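## Stochastic motor agents: kinesin-5 (Eg5) sliding motors restricted to
## antiparallel overlaps, kinesin-13 (KIF2A) diffusive minus-end
## depolymerases restricted to non-overlap lattice, and NuMA crosslinkers of
## parallel bridging microtubules.  The functions here are the per-entity
## update rules; the production simulator applies the same rules in
## compiled code.

#' Kinesin-5 (Eg5) parameters
#'
#' Load-dependent stepping follows Boltzmann load sharing:
#' \code{kF(F) = kF0 * exp(-theta * F * d / kBT)},
#' \code{kB(F) = kB0 * exp((1 - theta) * F * d / kBT)},
#' \code{koff(F) = koff0 * exp(F * d_off / kBT)}.
#' By default \code{kB0} is derived from the stall force
#' (\code{kF(stall) = kB(stall)}), and the unloaded sliding speed per head
#' pair is \code{(kF0 - kB0) * d}.
#'
#' @param kon_per_uM_s second-order binding rate to an overlap site
#'   (1/(uM s)).
#' @param conc_uM solution concentration (uM); the reservoir is unlimited.
#' @param koff0 unloaded unbinding rate of a bound head pair (1/s).
#' @param kF0,kB0 unloaded forward/backward stepping rates (1/s);
#'   \code{kB0 = NULL} derives it from \code{stall_pN}.
#' @param theta load-distribution factor in [0, 1].
#' @param stall_pN stall force (pN).
#' @param mu rebinding rate of a detached head pair while the partner pair
#'   stays bound (1/s).
#' @param d_nm tubulin step (nm).
#' @param kBT_pNnm thermal energy (pN nm).
#' @return An object of class \code{"eg5_params"}.
#' @export
eg5_params <- function(kon_per_uM_s = 0.01, conc_uM = 0.02, koff0 = 0.5,
                       kF0 = 2.5, kB0 = NULL, theta = 0.5, stall_pN = 6,
                       mu = 2, d_nm = 8, kBT_pNnm = 4.1) {
  if (is.null(kB0)) kB0 <- kF0 * exp(-stall_pN * d_nm / kBT_pNnm)
  stopifnot(kon_per_uM_s >= 0, conc_uM >= 0, koff0 >= 0, kF0 >= 0, kB0 >= 0,
            theta >= 0, theta <= 1, mu >= 0)
  structure(list(kon_per_uM_s = kon_per_uM_s, conc_uM = conc_uM,
                 koff0 = koff0, kF0 = kF0, kB0 = kB0, theta = theta,
                 stall_pN = stall_pN, mu = mu, d_nm = d_nm,
                 kBT_pNnm = kBT_pNnm),
            class = "eg5_params")
}

#' Load-dependent Eg5 rates
#'
#' @param F_load load on the head pair (pN), positive opposing forward
#'   stepping.
#' @param p an \code{\link{eg5_params}}.
#' @return List with \code{kF}, \code{kB}, \code{koff} (1/s).
#' @export
eg5_rates <- function(F_load, p = eg5_params()) {
  s <- F_load * p$d_nm / p$kBT_pNnm
  list(kF = p$kF0 * exp(-p$theta * s),
       kB = p$kB0 * exp((1 - p$theta) * s),
       koff = p$koff0 * exp(s))
}

#' Kinesin-13 (KIF2A) parameters
#'
#' A diffusive lattice-bound depolymerase.  Motors bind non-overlap sites,
#' diffuse with symmetric hop rate \code{kdiff}, are carried toward the
#' minus end by lattice turnover (poleward flux), and at the minus end
#' remove tubulins at \code{kdep} for up to \code{tau_end_s} before
#' detaching.
#'
#' @param kon_per_uM_s second-order per-site binding rate (1/(uM s)).
#' @param conc_uM solution concentration (uM).
#' @param kdiff symmetric hop rate along the lattice (1/s per direction).
#' @param koff unbinding rate anywhere on the lattice (1/s).
#' @param kdep tubulin removal rate while resident at the minus end (1/s).
#' @param tau_end_s maximum residence time at the minus end (s).
#' @return An object of class \code{"kif2a_params"}.
#' @export
kif2a_params <- function(kon_per_uM_s = 3e-2, conc_uM = 0.01, kdiff = 200,
                         koff = 0.002, kdep = 2.5, tau_end_s = 150) {
  stopifnot(kon_per_uM_s >= 0, conc_uM >= 0, kdiff >= 0, koff >= 0,
            kdep >= 0, tau_end_s >= 0)
  structure(list(kon_per_uM_s = kon_per_uM_s, conc_uM = conc_uM,
                 kdiff = kdiff, koff = koff, kdep = kdep,
                 tau_end_s = tau_end_s),
            class = "kif2a_params")
}

#' NuMA crosslinker parameters
#'
#' @param kon_per_uM_s second-order per-site binding rate of the first
#'   microtubule-binding domain (1/(uM s)).
#' @param conc_uM solution concentration (uM).
#' @param mu binding rate of the free second domain to the parallel
#'   bridging microtubule (1/s).
#' @param koff unbinding rate of a bound domain (1/s).
#' @return An object of class \code{"numa_params"}.
#' @export
numa_params <- function(kon_per_uM_s = 0.01, conc_uM = 0.02, mu = 10,
                        koff = 0.05) {
  stopifnot(kon_per_uM_s >= 0, conc_uM >= 0, mu >= 0, koff >= 0)
  structure(list(kon_per_uM_s = kon_per_uM_s, conc_uM = conc_uM, mu = mu,
                 koff = koff),
            class = "numa_params")
}

#' One stepping update of a bound Eg5 head pair
#'
#' Forward steps move the pair one site toward the plus end (increasing site
#' index; sites count from the minus end), backward steps the reverse.  A
#' step into an occupied or out-of-range site is suppressed for this tick
#' (site exclusion).
#'
#' @param site 1-based site index of the head pair.
#' @param occupancy integer occupancy vector of the lattice (0 = empty).
#' @param F_load load on the pair (pN).
#' @param p an \code{\link{eg5_params}}.
#' @param h time step (s).
#' @param u_f,u_b independent uniform deviates for the forward and backward
#'   trials.
#' @return The new site index.
#' @export
eg5_step <- function(site, occupancy, F_load = 0, p = eg5_params(), h = 1e-3,
                     u_f, u_b) {
  r <- eg5_rates(F_load, p)
  n <- length(occupancy)
  if (bernoulli_event(r$kF, h, u_f) && site < n &&
      occupancy[site + 1L] == 0L) {
    occupancy[site] <- 0L; site <- site + 1L; occupancy[site] <- OCC_EG5
  }
  if (bernoulli_event(r$kB, h, u_b) && site > 1L &&
      occupancy[site - 1L] == 0L) {
    occupancy[site] <- 0L; site <- site - 1L; occupancy[site] <- OCC_EG5
  }
  site
}

#' One diffusion/unbinding update of a lattice-bound KIF2A
#'
#' Two independent trials at the symmetric hop rate move the motor toward
#' the plus end and toward the minus end; a hop into an occupied,
#' out-of-range, or overlap site is suppressed.  A third trial detaches the
#' motor.
#'
#' @param site 1-based site index (site 1 is the minus end).
#' @param occupancy integer occupancy vector (0 = empty).
#' @param in_overlap logical vector marking antiparallel-overlap sites
#'   (forbidden to kinesin-13).
#' @param p a \code{\link{kif2a_params}}.
#' @param h time step (s).
#' @param u_f,u_b,u_off independent uniform deviates.
#' @return List with \code{site} and logical \code{detached}.
#' @export
kif2a_step <- function(site, occupancy, in_overlap = NULL,
                       p = kif2a_params(), h = 1e-3, u_f, u_b, u_off) {
  n <- length(occupancy)
  if (is.null(in_overlap)) in_overlap <- rep(FALSE, n)
  ok <- function(j) j >= 1L && j <= n && occupancy[j] == 0L && !in_overlap[j]
  if (bernoulli_event(p$kdiff, h, u_f) && ok(site + 1L)) {
    occupancy[site] <- 0L; site <- site + 1L; occupancy[site] <- OCC_KIF2A
  }
  if (bernoulli_event(p$kdiff, h, u_b) && ok(site - 1L)) {
    occupancy[site] <- 0L; site <- site - 1L; occupancy[site] <- OCC_KIF2A
  }
  detached <- bernoulli_event(p$koff, h, u_off)
  list(site = site, detached = detached)
}

#' Second-domain binding of a singly bound NuMA
#'
#' @param site site of the bound domain on its bridging microtubule.
#' @param occupancy_parallel occupancy vector of the parallel (same-pole)
#'   bridging microtubule.
#' @param p a \code{\link{numa_params}}.
#' @param h time step (s).
#' @param u uniform deviate.
#' @return The site bound on the parallel lattice (same index: parallel
#'   microtubules share orientation), or \code{NA_integer_} if the trial
#'   fails or the target site is unavailable.
#' @export
numa_bind_second <- function(site, occupancy_parallel, p = numa_params(),
                             h = 1e-3, u) {
  if (bernoulli_event(p$mu, h, u) && site <= length(occupancy_parallel) &&
      occupancy_parallel[site] == 0L) {
    return(site)
  }
  NA_integer_
}
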