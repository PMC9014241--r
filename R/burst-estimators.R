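#' Per-burst intensity FRET efficiency
#'
#' E = n_A / (n_A + n_D) from ideal (fully corrected) donor and acceptor
#' photon counts.
#'
#' @param n_acceptor acceptor photon count(s).
#' @param n_donor donor photon count(s).
#' @return Efficiency in [0, 1] (vectorized).
#' @export
burst_efficiency <- function(n_acceptor, n_donor) {
  tot <- n_acceptor + n_donor
  if (any(tot <= 0)) stop("burst has zero photons: efficiency undefined")
  n_acceptor / tot
}

#' Per-burst mean donor delay time
#'
#' The arithmetic mean of the donor TCSPC delay times. In the ideal
#' delta-pulse, zero-background regime this equals the maximum-likelihood
#' lifetime estimate, and its expectation is the intensity-weighted
#' lifetime m2/m1 of the burst's lifetime mixture -- not the species mean.
#'
#' @param donor_delays numeric vector of donor delay times (ns), >= 1.
#' @return Estimated tauF in ns.
#' @export
burst_mean_delay <- function(donor_delays) {
  donor_delays <- donor_delays[!is.na(donor_delays)]
  if (length(donor_delays) == 0L)
    stop("no donor photons: lifetime undefined for this burst")
  mean(donor_delays)
}

#' BVA standard deviation of the FRET efficiency
#'
#' Burst variance analysis: the photon sequence of a burst is cut into
#' consecutive windows of N photons (non-overlapping by default, trailing
#' partial window discarded), a window efficiency E_i is computed for each,
#' and the root-mean-square deviation of the E_i from the whole-burst
#' efficiency is returned.
#'
#' @param photon_colors character or logical vector in photon order:
#'   \code{"A"}/\code{TRUE} for acceptor, \code{"D"}/\code{FALSE} for donor.
#' @param N photons per window (default 5).
#' @param overlap if \code{TRUE}, use all sliding windows instead of
#'   disjoint ones.
#' @return sigma_E for the burst.
#' @export
bva_sigma <- function(photon_colors, N = 5, overlap = FALSE) {
  acc <- if (is.character(photon_colors)) photon_colors == "A"
         else as.logical(photon_colors)
  n <- length(acc)
  if (n < N) stop("fewer photons than one BVA window")
  E_burst <- mean(acc)
  if (overlap) {
    cs <- cumsum(c(0, acc))
    Ei <- (cs[(N + 1):(n + 1)] - cs[1:(n - N + 1)]) / N
  } else {
    M <- n %/% N
    idx <- seq_len(M * N)
    Ei <- colMeans(matrix(acc[idx], nrow = N))
  }
  sqrt(mean((Ei - E_burst)^2))
}

#' BVA shot-noise reference
#'
#' The binomial shot-noise limit sigma_E = sqrt(E (1 - E) / N): the static
#' reference line of burst variance analysis. Bursts whose BVA standard
#' deviation exceeds it are considered dynamic.
#'
#' @param E burst FRET efficiency (vectorized).
#' @param N photons per BVA window.
#' @return sigma_E at the shot-noise limit.
#' @export
bva_shot_noise <- function(E, N = 5) {
  stopifnot(N >= 1)
  sqrt(E * (1 - E) / N)
}

#' FRET-efficiency variance from the observables
#'
#' Var_c(E) = (1 - E)(E - E_tau) with E_tau = 1 - tauF/tau_D0: the pure
#' conformational-dynamics variance implied by the displacement of a burst
#' from the static FRET-line, with no shot-noise contribution. For
#' two-state exchange it traces the parabola
#' Var(E) = (taubar - tau1)(tau2 - taubar)/tau_D0^2.
#'
#' @param obs list with \code{E} and \code{tauF} (vectorized fields).
#' @param ctx a [fret_context()].
#' @return Variance of E (dimensionless).
#' @export
dynamic_variance_estimate <- function(obs, ctx) {
  ctx <- as_fret_context(ctx)
  E_tau <- 1 - obs$tauF / ctx$tau_D0
  (1 - obs$E) * (obs$E - E_tau)
}

#' Approximate dynamic variance from BVA
#'
#' sigma_BVA^2 - E(1 - E)/N, floored at zero. Approximate only: shot noise
#' and dynamics contributions to the BVA variance are not strictly
#' additive, and the windowed averaging makes BVA underestimate the
#' conformational variance. Degenerates at N = 1 (every window efficiency
#' is 0 or 1), which is rejected.
#'
#' @param sigmaE_bva BVA standard deviation(s).
#' @param E burst efficiency(ies).
#' @param N photons per window, > 1.
#' @return Approximate Var_c(E), >= 0.
#' @export
bva_shot_noise_subtraction <- function(sigmaE_bva, E, N = 5) {
  if (N <= 1) stop("N = 1 windows are degenerate (E_i is always 0 or 1)")
  pmax(sigmaE_bva^2 - E * (1 - E) / N, 0)
}

#' Per-burst observables of a burst table
#'
#' Computes, for every burst of a [simulate_experiment()] result (or a
#' photon table read back from file), the intensity FRET efficiency, the
#' mean-delay lifetime, the BVA standard deviation, the
#' variance-from-observables dynamics estimate and the moment difference.
#' Bursts without donor photons get \code{NA} lifetime-derived columns;
#' bursts with fewer than N photons get \code{NA} BVA.
#'
#' @param bt a \code{burst_table}, or a photon data.frame with columns
#'   \code{burst_id}, \code{channel}, \code{delay_ns}.
#' @param ctx a [fret_context()] (taken from the burst table if omitted).
#' @param N BVA window size.
#' @param tau_norm normalization lifetime for Gamma; defaults to
#'   \code{ctx$tau_D0} (pass the donor-mixture intensity-weighted lifetime
#'   when a multi-exponential donor is declared).
#' @return data.frame with one row per burst: \code{burst_id},
#'   \code{n_donor}, \code{n_acceptor}, \code{E_hat}, \code{tauF_hat},
#'   \code{sigmaE_bva}, \code{var_dyn}, \code{Gamma_hat}.
#' @export
burst_observables <- function(bt, ctx = NULL, N = 5, tau_norm = NULL) {
  ph <- if (inherits(bt, "burst_table")) bt$photons else bt
  if (is.null(ctx) && inherits(bt, "burst_table")) ctx <- bt$context
  ctx <- as_fret_context(ctx)
  if (is.null(tau_norm)) tau_norm <- ctx$tau_D0
  ids <- unique(ph$burst_id)
  rows <- lapply(ids, function(b) {
    p <- ph[ph$burst_id == b, ]
    nA <- sum(p$channel == "A"); nD <- sum(p$channel == "D")
    E <- burst_efficiency(nA, nD)
    tauF <- if (nD > 0) burst_mean_delay(p$delay_ns) else NA_real_
    sE <- if (nrow(p) >= N) bva_sigma(p$channel, N) else NA_real_
    vd <- if (!is.na(tauF))
      dynamic_variance_estimate(list(E = E, tauF = tauF), ctx)
      else NA_real_
    G <- if (!is.na(tauF)) (1 - E) * (1 - tauF / tau_norm) else NA_real_
    data.frame(burst_id = b, n_donor = nD, n_acceptor = nA, E_hat = E,
               tauF_hat = tauF, sigmaE_bva = sE, var_dyn = vd,
               Gamma_hat = G)
  })
  out <- do.call(rbind, rows)
  n_no_donor <- sum(is.na(out$tauF_hat))
  if (n_no_donor > 0)
    message(n_no_donor, " burst(s) without donor photons excluded from ",
            "lifetime-derived columns")
  out
}

#' Two-dimensional burst histogram
#'
#' Bins per-burst observables in one of three representations:
#' \code{"E_tauF"} (tauF vs E), \code{"moment"} (E vs Gamma) or
#' \code{"mean_variance"} (E vs Var_c(E)). Axis transforms are exactly the
#' observable transforms used everywhere else, applied per burst, so burst
#' identity and total count are preserved. Marginal counts are included.
#'
#' @param obs data.frame from [burst_observables()].
#' @param representation which axes to histogram.
#' @param bins number of bins per axis (length 1 or 2).
#' @param xlim,ylim optional axis ranges; defaults cover the data.
#' @return List with \code{counts} (matrix, x by y), \code{x_breaks},
#'   \code{y_breaks}, \code{x_marginal}, \code{y_marginal},
#'   \code{n} (bursts binned) and the axis \code{labels}.
#' @export
histogram2d <- function(obs, representation = c("E_tauF", "moment",
                                                "mean_variance"),
                        bins = 41, xlim = NULL, ylim = NULL) {
  representation <- match.arg(representation)
  stopifnot(nrow(obs) >= 1)
  bins <- rep_len(bins, 2L)
  xy <- switch(representation,
    E_tauF = list(x = obs$tauF_hat, y = obs$E_hat,
                  labels = c("tauF_ns", "E")),
    moment = list(x = obs$E_hat, y = obs$Gamma_hat,
                  labels = c("E", "Gamma")),
    mean_variance = list(x = obs$E_hat, y = obs$var_dyn,
                         labels = c("E", "var_E")))
  keep <- is.finite(xy$x) & is.finite(xy$y)
  if (!any(keep))
    stop("no finite observations to bin in representation '",
         representation, "'")
  x <- xy$x[keep]; y <- xy$y[keep]
  if (is.null(xlim)) xlim <- range(x)
  if (is.null(ylim)) ylim <- range(y)
  xb <- seq(xlim[1], xlim[2], length.out = bins[1] + 1L)
  yb <- seq(ylim[1], ylim[2], length.out = bins[2] + 1L)
  xi <- findInterval(x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1], bins[2])
  for (i in seq_along(xi))
    counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1L
  list(counts = counts, x_breaks = xb, y_breaks = yb,
       x_marginal = rowSums(counts), y_marginal = colSums(counts),
       n = length(x), labels = xy$labels)
}
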