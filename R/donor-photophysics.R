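#' Multi-exponential donor (donor-only lifetime mixture)
#'
#' A donor fluorophore with several photophysical states, e.g. a quenched
#' and an unquenched species. Each state has its own donor-only lifetime
#' and fluorescence quantum yield. When the radiative rate is shared
#' between the states, quantum yields are proportional to lifetimes; a
#' violation of that proportionality is reported as a warning, not an
#' error, since static quenching breaks it legitimately.
#'
#' @param lifetimes donor-only lifetimes tau_D0(j) in ns.
#' @param fractions species fractions x_D0(j), summing to 1.
#' @param quantum_yields donor fluorescence quantum yields Phi_F,D(j).
#' @return An object of class \code{"donor_mixture"}.
#' @examples
#' donor_mixture(c(4, 1), c(0.25, 0.75), c(0.8, 0.2))
#' @export
donor_mixture <- function(lifetimes, fractions, quantum_yields) {
  stopifnot(length(lifetimes) == length(fractions),
            length(lifetimes) == length(quantum_yields))
  if (any(lifetimes <= 0)) stop("donor lifetimes must be positive")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(quantum_yields <= 0 | quantum_yields > 1))
    stop("quantum yields must lie in (0, 1]")
  ratio <- quantum_yields / lifetimes
  if (length(ratio) > 1 && diff(range(ratio)) > 1e-6 * mean(ratio))
    warning("quantum yields are not proportional to lifetimes; ",
            "shared radiative rate assumption does not hold")
  structure(list(lifetimes = as.numeric(lifetimes),
                 fractions = as.numeric(fractions),
                 quantum_yields = as.numeric(quantum_yields)),
            class = "donor_mixture")
}

#' Discrete distribution of FRET rates
#'
#' FRET-rate states k_RET(i) with fractions x_RET(i); used with a
#' [donor_mixture()] under the homogeneous approximation, in which the
#' joint distribution of donor and FRET states factorizes.
#'
#' @param rates FRET rate constants in 1/ns, >= 0.
#' @param fractions fractions summing to 1.
#' @return An object of class \code{"fret_rate_set"}.
#' @export
fret_rate_set <- function(rates, fractions) {
  stopifnot(length(rates) == length(fractions))
  if (any(rates < 0)) stop("rates must be non-negative")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(rates = as.numeric(rates), fractions = as.numeric(fractions)),
            class = "fret_rate_set")
}

#' Lifetimes of the donor x FRET product states
#' @noRd
joint_lifetimes <- function(donor, fret) {
  outer(fret$rates, donor$lifetimes,
        function(k, t0) 1 / (1 / t0 + k))   # [i, j]: FRET state i, donor j
}

#' Lifetime moments over donor and FRET states
#'
#' Double sum over the product space of donor photophysical states j and
#' FRET states i, with joint lifetimes
#' tau_ij = 1 / (1/tau_D0(j) + k_RET(i)) and factorized weights
#' x_D0(j) x_RET(i) (homogeneous approximation: the FRET rate does not
#' depend on the donor state).
#'
#' @param donor a [donor_mixture()].
#' @param fret a [fret_rate_set()].
#' @return A [moment_pair()].
#' @export
joint_moments <- function(donor, fret) {
  stopifnot(inherits(donor, "donor_mixture"), inherits(fret, "fret_rate_set"))
  tau <- joint_lifetimes(donor, fret)
  w <- outer(fret$fractions, donor$fractions)
  moment_pair(sum(w * tau), sum(w * tau^2))
}

#' Effective donor-only lifetime under quenching
#'
#' tau_D0' = tau_DA + gamma' (tau_D0 - tau_DA) with
#' gamma' = Phi_F,A / Phi_F,D: the donor-only lifetime that makes the
#' intensity-based proximity ratio consistent with photon counts when donor
#' and acceptor quantum yields differ. gamma' = 1 returns tau_D0 unchanged;
#' gamma' -> 0 collapses to tau_DA.
#'
#' @param tauDA FRET-quenched donor lifetime (ns).
#' @param tauD0 donor-only lifetime (ns).
#' @param gamma_prime quantum-yield ratio Phi_F,A / Phi_F,D, > 0.
#' @return Effective lifetime in ns.
#' @export
effective_donor_lifetime <- function(tauDA, tauD0, gamma_prime) {
  if (any(gamma_prime <= 0)) stop("'gamma_prime' must be positive")
  tauDA + gamma_prime * (tauD0 - tauDA)
}

#' Intensity-weighted donor-only lifetime of a mixture
#'
#' tau_D0F = m2/m1 of the donor-only lifetime distribution; the
#' normalization lifetime for the moment difference in donor-mixture
#' contexts, and the tauF-axis intercept of the fast-exchange static line.
#'
#' @param donor a [donor_mixture()].
#' @return Lifetime in ns.
#' @export
donor_intensity_weighted_lifetime <- function(donor) {
  m1 <- sum(donor$fractions * donor$lifetimes)
  sum(donor$fractions * donor$lifetimes^2) / m1
}

#' Proximity ratio of a donor-mixture FRET system
#'
#' When the donor has several photophysical states, photon intensities
#' weight the states by their quantum yields and no single distance-related
#' efficiency exists. The proximity ratio
#' E_PR = 1 - <tau_DA>_x / <tau_D0'>_x averages the quenched and effective
#' donor-only lifetimes over all donor x FRET product states, with
#' gamma'(j) = Phi_F,A / Phi_F,D(j) per donor species. For a single donor
#' state with gamma' = 1 it reduces to the intensity FRET efficiency.
#'
#' @param donor a [donor_mixture()].
#' @param fret a [fret_rate_set()].
#' @param ctx a [fret_context()] with the acceptor quantum yield set.
#' @return Proximity ratio (dimensionless).
#' @export
proximity_ratio <- function(donor, fret, ctx) {
  ctx <- as_fret_context(ctx)
  if (is.null(ctx$phi_A))
    stop("acceptor quantum yield 'phi_A' must be set in the context")
  tau <- joint_lifetimes(donor, fret)              # [i, j]
  gp <- ctx$phi_A / donor$quantum_yields           # gamma'(j)
  # tau_eff[i, j] = tau_ij + gamma'(j) * (tauD0(j) - tau_ij)
  tau_eff <- tau + sweep(sweep(-tau, 2, donor$lifetimes, `+`), 2, gp, `*`)
  w <- outer(fret$fractions, donor$fractions)
  1 - sum(w * tau) / sum(w * tau_eff)
}

#' Static line for fast donor-state exchange
#'
#' When donor photophysical states exchange much faster than the
#' observation time, every burst averages over the donor states and a
#' single convex static line results in the (E_PR, tauF) plane. The line is
#' generated by sweeping one FRET rate k_RET over a logarithmic grid, fully
#' averaging lifetimes and effective donor-only lifetimes over the donor
#' states at each point. At k_RET = 0 the line intercepts the tauF axis at
#' the intensity-weighted donor-only lifetime of the mixture; the moment
#' difference is normalized by the same lifetime.
#'
#' @param donor a [donor_mixture()].
#' @param ctx a [fret_context()] with \code{phi_A} set.
#' @param n_points samples on the rate grid.
#' @param k_range range of k_RET in units of 1/tau_D0,max (log-spaced);
#'   the endpoints k = 0 and the pure donor-only point are always included.
#' @return A [fret_line()] of kind \code{"static_PR_fast"} parameterized by
#'   k_RET (1/ns).
#' @export
static_line_fast_exchange <- function(donor, ctx, n_points = 201,
                                      k_range = c(1e-4, 1e4)) {
  ctx <- as_fret_context(ctx)
  stopifnot(inherits(donor, "donor_mixture"))
  k0 <- 1 / max(donor$lifetimes)
  ks <- c(0, k0 * 10^seq(log10(k_range[1]), log10(k_range[2]),
                         length.out = n_points - 1))
  tauD0F <- donor_intensity_weighted_lifetime(donor)
  gp <- if (is.null(ctx$phi_A)) rep(1, length(donor$lifetimes))
        else ctx$phi_A / donor$quantum_yields
  rows <- lapply(ks, function(k) {
    tau <- 1 / (1 / donor$lifetimes + k)
    tau_eff <- tau + gp * (donor$lifetimes - tau)
    m1 <- sum(donor$fractions * tau)
    m2 <- sum(donor$fractions * tau^2)
    EPR <- 1 - m1 / sum(donor$fractions * tau_eff)
    c(EPR, m1, m2)
  })
  rows <- do.call(rbind, rows)
  tauF <- rows[, 3] / rows[, 2]
  samples <- data.frame(param = ks, E = rows[, 1], tauF_ns = tauF,
                        Gamma = (1 - rows[, 1]) * (1 - tauF / tauD0F),
                        m1_ns = rows[, 2], m2_ns2 = rows[, 3])
  fret_line(samples, "static_PR_fast", "kRET", ctx,
            model = list(donor = donor, tau_D0F = tauD0F),
            tau_norm = tauD0F)
}

#' Static line of one donor species under slow exchange
#'
#' When donor states exchange slower than the observation time each burst
#' sees a single donor species, and each species has its own static line in
#' the (E_PR, tauF) plane. The curvature comes from gamma' differing from
#' 1 in the proximity ratio; with gamma' = 1 the line collapses onto the
#' ideal static line. The moment difference is normalized by the
#' intensity-weighted donor-only lifetime of the full mixture, so it can go
#' negative for the short-lifetime species.
#'
#' @param donor a [donor_mixture()] (defines the Gamma normalization).
#' @param j index of the donor species whose line is generated.
#' @param ctx a [fret_context()] with \code{phi_A} set.
#' @param n_points samples, uniform in the species efficiency.
#' @return A [fret_line()] of kind \code{"static_PR_slow"}.
#' @export
static_line_slow_exchange <- function(donor, j, ctx, n_points = 201) {
  ctx <- as_fret_context(ctx)
  stopifnot(inherits(donor, "donor_mixture"),
            j >= 1, j <= length(donor$lifetimes))
  tauD0j <- donor$lifetimes[j]
  gp <- if (is.null(ctx$phi_A)) 1 else ctx$phi_A / donor$quantum_yields[j]
  tauD0F <- donor_intensity_weighted_lifetime(donor)
  tau <- seq(tauD0j, 0, length.out = n_points)     # quenched lifetime sweep
  tau_eff <- tau + gp * (tauD0j - tau)
  EPR <- ifelse(tau_eff > 0, 1 - tau / tau_eff, 1)
  samples <- data.frame(param = tau, E = EPR, tauF_ns = tau,
                        Gamma = (1 - EPR) * (1 - tau / tauD0F),
                        m1_ns = tau, m2_ns2 = tau^2)
  fret_line(samples, "static_PR_slow", "tauDA", ctx,
            model = list(j = j, tau_D0j = tauD0j, gamma_prime = gp,
                         tau_D0F = tauD0F),
            tau_norm = tauD0F)
}

#' Dynamic FRET-line with a multi-exponential donor
#'
#' Two conformational states, each with a fixed FRET rate, on a donor with
#' several photophysical states: the joint moments of each conformational
#' state (enumerated over all donor x conformation components) are mixed
#' linearly in the conformational fraction x1. The resulting line is
#' straight in the moment representation for both exchange regimes; for
#' slow donor exchange pass a single-species [donor_mixture()] to obtain
#' the per-species line.
#'
#' @param s1,s2 [fret_state()] objects (efficiencies interpreted on the
#'   reference donor state, i.e. converted to FRET rates via the context).
#' @param donor a [donor_mixture()].
#' @param ctx a [fret_context()] with \code{phi_A} set.
#' @param exchange \code{"fast"} or \code{"slow"}; recorded in metadata
#'   (the moment mixing is identical, see Details).
#' @param n_points samples, uniform in x1.
#' @return A [fret_line()] of kind \code{"dynamic"} with proximity-ratio
#'   observables, Gamma normalized by the donor-mixture tau_D0F.
#' @export
dynamic_line_PR <- function(s1, s2, donor, ctx,
                            exchange = c("fast", "slow"), n_points = 201) {
  exchange <- match.arg(exchange)
  ctx <- as_fret_context(ctx)
  stopifnot(inherits(donor, "donor_mixture"))
  k1 <- pr_state_rate(s1, ctx); k2 <- pr_state_rate(s2, ctx)
  gp <- if (is.null(ctx$phi_A)) rep(1, length(donor$lifetimes))
        else ctx$phi_A / donor$quantum_yields
  tauD0F <- donor_intensity_weighted_lifetime(donor)
  comp <- function(k) {   # per-conformation donor-averaged quantities
    tau <- 1 / (1 / donor$lifetimes + k)
    tau_eff <- tau + gp * (donor$lifetimes - tau)
    c(m1 = sum(donor$fractions * tau),
      m2 = sum(donor$fractions * tau^2),
      d = sum(donor$fractions * tau_eff))
  }
  c1 <- comp(k1); c2 <- comp(k2)
  x1 <- seq(1, 0, length.out = n_points)
  m1 <- x1 * c1["m1"] + (1 - x1) * c2["m1"]
  m2 <- x1 * c1["m2"] + (1 - x1) * c2["m2"]
  dd <- x1 * c1["d"] + (1 - x1) * c2["d"]
  EPR <- 1 - m1 / dd
  tauF <- m2 / m1
  samples <- data.frame(param = x1, E = EPR, tauF_ns = tauF,
                        Gamma = (1 - EPR) * (1 - tauF / tauD0F),
                        m1_ns = m1, m2_ns2 = m2)
  fret_line(samples, "dynamic", "x1", ctx,
            model = list(k1 = k1, k2 = k2, donor = donor,
                         exchange = exchange, tau_D0F = tauD0F),
            tau_norm = tauD0F)
}

#' FRET rate of a conformational state on the reference donor
#' @noRd
pr_state_rate <- function(s, ctx) {
  if (!is.null(s$Rmp)) return(ret_rate(s$Rmp, ctx))
  E <- s$E
  if (E >= 1) stop("E = 1 implies an infinite FRET rate")
  # k such that E = k / (k + 1/tauD0) on the reference donor
  (E / (1 - E)) / ctx$tau_D0
}
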