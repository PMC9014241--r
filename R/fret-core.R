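#' Experimental context for FRET calculations
#'
#' Bundles the dye-pair constants every FRET-line needs: the Foerster radius
#' \code{R0}, the donor-only fluorescence lifetime \code{tau_D0}, and
#' (optionally, for bookkeeping) the donor radiative rate and the donor and
#' acceptor fluorescence quantum yields. All implemented formulas use
#' \code{tau_D0} and quantum-yield ratios only, so the absolute radiative
#' rate never enters the numerics.
#'
#' Units are fixed throughout the package: distances in Angstrom, times and
#' lifetimes in nanoseconds, rates in 1/ns (kinetic exchange rates in 1/ms
#' where stated).
#'
#' @param R0 Foerster radius in Angstrom (distance of 50\% transfer
#'   efficiency). Must be positive.
#' @param tau_D0 donor-only fluorescence lifetime in ns. Must be positive.
#' @param kF_D optional donor radiative rate constant in 1/ns (informational).
#' @param phi_D optional donor fluorescence quantum yield in (0, 1].
#' @param phi_A optional acceptor fluorescence quantum yield in (0, 1].
#' @return An object of class \code{"fret_context"}.
#' @examples
#' ctx <- fret_context(R0 = 50, tau_D0 = 4)
#' efficiency_from_distance(60, ctx)
#' @export
fret_context <- function(R0, tau_D0, kF_D = NULL, phi_D = NULL, phi_A = NULL) {
  stopifnot(is.numeric(R0), length(R0) == 1L, is.finite(R0),
            is.numeric(tau_D0), length(tau_D0) == 1L, is.finite(tau_D0))
  if (R0 <= 0) stop("'R0' must be positive (Angstrom)")
  if (tau_D0 <= 0) stop("'tau_D0' must be positive (ns)")
  for (nm in c("phi_D", "phi_A")) {
    v <- get(nm)
    if (!is.null(v) && (v <= 0 || v > 1))
      stop(sprintf("'%s' must lie in (0, 1]", nm))
  }
  structure(list(R0 = R0, tau_D0 = tau_D0, kF_D = kF_D,
                 phi_D = phi_D, phi_A = phi_A),
            class = "fret_context")
}

#' @export
print.fret_context <- function(x, ...) {
  cat("FRET context: R0 =", x$R0, "A, tau_D0 =", x$tau_D0, "ns\n")
  if (!is.null(x$phi_D)) cat("  donor quantum yield:", x$phi_D, "\n")
  if (!is.null(x$phi_A)) cat("  acceptor quantum yield:", x$phi_A, "\n")
  invisible(x)
}

as_fret_context <- function(x) {
  if (!inherits(x, "fret_context")) stop("expected a 'fret_context' object")
  x
}

#' Discrete lifetime mixture
#'
#' A discrete distribution of donor fluorescence lifetimes: species with
#' lifetimes \code{lifetimes} occur with fractions \code{fractions}.
#' Fractions must sum to 1 within 1e-9; by default a violation is an error
#' rather than being silently renormalized, so caller bugs are not masked.
#'
#' @param lifetimes numeric vector of lifetimes (ns), all >= 0.
#' @param fractions numeric vector of species fractions, same length,
#'   all >= 0, summing to 1.
#' @param renormalize if \code{TRUE}, rescale fractions to sum to exactly 1
#'   instead of raising an error when the sum is off by more than 1e-9.
#' @return An object of class \code{"lifetime_mixture"}.
#' @export
lifetime_mixture <- function(lifetimes, fractions, renormalize = FALSE) {
  stopifnot(is.numeric(lifetimes), is.numeric(fractions),
            length(lifetimes) == length(fractions), length(lifetimes) >= 1L)
  if (any(lifetimes < 0)) stop("lifetimes must be non-negative")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9) {
    if (renormalize) fractions <- fractions / s
    else stop(sprintf("fractions sum to %.12g, not 1 (tolerance 1e-9)", s))
  }
  structure(list(lifetimes = as.numeric(lifetimes),
                 fractions = as.numeric(fractions)),
            class = "lifetime_mixture")
}

#' First and second lifetime moments
#'
#' Container for the first moment \code{m1} (ns) and second moment \code{m2}
#' (ns^2) of a lifetime distribution. Enforces the Cauchy-Schwarz bound
#' m2 >= m1^2 (non-negative variance) up to a small numerical tolerance.
#'
#' @param m1 first moment (ns), >= 0.
#' @param m2 second moment (ns^2), >= m1^2 - tol.
#' @param tol tolerance for the variance bound.
#' @return A list of class \code{"moment_pair"} with fields \code{m1}, \code{m2}.
#' @export
moment_pair <- function(m1, m2, tol = 1e-9) {
  stopifnot(is.numeric(m1), is.numeric(m2), length(m1) == 1L, length(m2) == 1L)
  if (m1 < 0) stop("first moment must be non-negative")
  if (m2 < m1^2 - tol * max(1, m1^2))
    stop("second moment violates m2 >= m1^2 (negative variance)")
  structure(list(m1 = m1, m2 = m2), class = "moment_pair")
}

#' FRET efficiency from inter-dye distance
#'
#' The Foerster relation E = 1 / (1 + (R/R0)^6): efficiency 1/2 at R = R0,
#' strictly decreasing in R.
#'
#' @param R_DA inter-dye distance(s) in Angstrom, >= 0 (vectorized).
#' @param ctx a [fret_context()].
#' @return FRET efficiency in [0, 1].
#' @export
efficiency_from_distance <- function(R_DA, ctx) {
  ctx <- as_fret_context(ctx)
  if (any(R_DA < 0)) stop("distance must be non-negative")
  1 / (1 + (R_DA / ctx$R0)^6)
}

#' Inter-dye distance from FRET efficiency
#'
#' Inverse of the Foerster relation; defined for E strictly inside (0, 1)
#' (E = 0 maps to infinite and E = 1 to zero distance).
#'
#' @param E FRET efficiency, 0 < E < 1 (vectorized).
#' @param ctx a [fret_context()].
#' @return Distance in Angstrom.
#' @export
distance_from_efficiency <- function(E, ctx) {
  ctx <- as_fret_context(ctx)
  if (any(E <= 0) || any(E >= 1))
    stop("efficiency must lie strictly in (0, 1) for a finite distance")
  ctx$R0 * (1 / E - 1)^(1 / 6)
}

#' Donor lifetime in the presence of FRET
#'
#' tau_DA = (1 - E) tau_D0: the quenched donor lifetime of a state with
#' efficiency E.
#'
#' @param E FRET efficiency in [0, 1] (vectorized).
#' @param ctx a [fret_context()].
#' @return Lifetime in ns.
#' @export
lifetime_from_efficiency <- function(E, ctx) {
  ctx <- as_fret_context(ctx)
  if (any(E < 0) || any(E > 1)) stop("efficiency must lie in [0, 1]")
  (1 - E) * ctx$tau_D0
}

#' Energy-transfer rate constant
#'
#' k_RET = (1 / tau_D0) (R0 / R)^6, the rate of donor-to-acceptor energy
#' transfer at inter-dye distance R.
#'
#' @param R_DA inter-dye distance in Angstrom, > 0 (vectorized).
#' @param ctx a [fret_context()].
#' @return Rate in 1/ns.
#' @export
ret_rate <- function(R_DA, ctx) {
  ctx <- as_fret_context(ctx)
  if (any(R_DA <= 0)) stop("distance must be positive (rate diverges at 0)")
  (1 / ctx$tau_D0) * (ctx$R0 / R_DA)^6
}

#' Moments of a discrete lifetime mixture
#'
#' m1 = sum x_i tau_i and m2 = sum x_i tau_i^2; both are linear in the
#' species fractions, which is what makes dynamic FRET-lines straight in the
#' moment representation.
#'
#' @param mix a [lifetime_mixture()].
#' @return A [moment_pair()].
#' @export
mixture_moments <- function(mix) {
  stopifnot(inherits(mix, "lifetime_mixture"))
  m1 <- sum(mix$fractions * mix$lifetimes)
  m2 <- sum(mix$fractions * mix$lifetimes^2)
  moment_pair(m1, m2)
}

#' Intensity-weighted average lifetime
#'
#' tau_F = m2 / m1, the ratio of second to first lifetime moments. This is
#' what the mean TCSPC delay time (and the maximum-likelihood lifetime fit)
#' measures; it exceeds the species-weighted mean m1 whenever the lifetime
#' distribution has non-zero variance.
#'
#' @param m a [moment_pair()] (or list with \code{m1}, \code{m2}).
#' @return Lifetime in ns.
#' @export
intensity_weighted_lifetime <- function(m) {
  if (m$m1 <= 0) stop("first moment must be positive for tau_F = m2/m1")
  m$m2 / m$m1
}

#' Observables from lifetime moments
#'
#' Maps (m1, m2) to the experimental observables E = 1 - m1/tau_D0 and
#' tau_F = m2/m1.
#'
#' @param m a [moment_pair()].
#' @param ctx a [fret_context()].
#' @return List with \code{E} and \code{tauF} (ns).
#' @export
moments_to_observables <- function(m, ctx) {
  ctx <- as_fret_context(ctx)
  E <- 1 - m$m1 / ctx$tau_D0
  tauF <- if (m$m1 > 1e-12) m$m2 / m$m1 else 0
  list(E = E, tauF = tauF)
}

#' Lifetime moments from observables
#'
#' Inverse transform of [moments_to_observables()]: m1 = (1 - E) tau_D0 and
#' m2 = tau_F m1. This is how linker-averaged state moments are read off
#' measured pure-state populations without a linker model.
#'
#' @param obs list with \code{E} and \code{tauF} (ns).
#' @param ctx a [fret_context()].
#' @return A [moment_pair()].
#' @export
observables_to_moments <- function(obs, ctx) {
  ctx <- as_fret_context(ctx)
  if (obs$E < 0 || obs$E > 1) stop("efficiency must lie in [0, 1]")
  if (obs$tauF < 0) stop("tauF must be non-negative")
  m1 <- (1 - obs$E) * ctx$tau_D0
  moment_pair(m1, obs$tauF * m1, tol = 1e-6)
}

#' Lifetime-distribution variance from observables
#'
#' Var(tau_DA) = (1 - E)(E - E_tau) tau_D0^2 with E_tau = 1 - tau_F/tau_D0;
#' identical to m2 - m1^2 of the underlying lifetime distribution. The
#' corresponding FRET-efficiency variance is Var(E) = Var(tau)/tau_D0^2.
#'
#' @param obs list with \code{E} and \code{tauF} (ns).
#' @param ctx a [fret_context()].
#' @param tol negative values beyond \code{-tol} raise an error (a physical
#'   lifetime distribution cannot have negative variance).
#' @return Variance in ns^2 (possibly slightly negative within \code{tol}).
#' @export
lifetime_variance <- function(obs, ctx, tol = 1e-9) {
  ctx <- as_fret_context(ctx)
  E_tau <- 1 - obs$tauF / ctx$tau_D0
  v <- (1 - obs$E) * (obs$E - E_tau) * ctx$tau_D0^2
  if (v < -tol * ctx$tau_D0^2)
    stop("negative lifetime variance: observables are unphysical ",
         "(point left of the static FRET-line)")
  v
}

#' Moment difference Gamma
#'
#' Gamma = (1 - E)(1 - tau_F/tau_D0) = m1/tau_D0 - m2/tau_D0^2, the
#' difference of the normalized first and second lifetime moments. In this
#' representation the static FRET-line becomes the parabola (1 - E) E with
#' maximum (1/2, 1/4), and all kinetic mixing lines become straight.
#' Negative values occur for donor mixtures normalized by the
#' intensity-weighted donor-only lifetime.
#'
#' @param obs list with \code{E} and \code{tauF} (ns), vectorized fields.
#' @param ctx a [fret_context()].
#' @return Dimensionless moment difference.
#' @export
moment_difference <- function(obs, ctx) {
  ctx <- as_fret_context(ctx)
  (1 - obs$E) * (1 - obs$tauF / ctx$tau_D0)
}

#' Fluorescence decay of a lifetime mixture
#'
#' Unit-amplitude multi-exponential decay sum x_i exp(-t/tau_i) on a time
#' grid. Its time integral equals the first moment of the mixture.
#'
#' @param mix a [lifetime_mixture()].
#' @param t_grid non-negative, increasing time grid (ns).
#' @return Numeric vector of intensities, 1 at t = 0.
#' @export
decay_from_lifetime_mixture <- function(mix, t_grid) {
  stopifnot(inherits(mix, "lifetime_mixture"))
  if (any(t_grid < 0)) stop("time grid must be non-negative")
  if (is.unsorted(t_grid)) stop("time grid must be increasing")
  vapply(t_grid, function(t) sum(mix$fractions * exp(-t / mix$lifetimes)),
         numeric(1))
}

#' Draw TCSPC delay times from a lifetime mixture
#'
#' Samples photon delay times from the normalized decay of a mixture: a
#' species is chosen with probability proportional to x_i tau_i (its
#' relative photon yield), then an exponential delay with that species'
#' lifetime is drawn. The expectation of the sample mean is m2/m1, the
#' intensity-weighted lifetime -- not the species mean m1.
#'
#' @param n number of delays to draw.
#' @param mix a [lifetime_mixture()].
#' @return Numeric vector of delay times (ns).
#' @export
sample_delay_times <- function(n, mix) {
  stopifnot(inherits(mix, "lifetime_mixture"))
  w <- mix$fractions * mix$lifetimes
  if (sum(w) <= 0) stop("mixture has zero total intensity")
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  stats::rexp(n, rate = 1 / mix$lifetimes[idx])
}
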