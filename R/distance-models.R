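#' Inter-dye distance distribution models
#'
#' Probability densities of the inter-dye distance R >= 0 used to build
#' linker-broadened and polymer FRET-lines:
#' \describe{
#'   \item{chi}{non-central chi distribution (3 spatial dof) with the
#'     mean-position distance \code{Rmp} as non-centrality and per-axis
#'     width \code{sigma}; the physical model of two isotropically
#'     distributed dye clouds.}
#'   \item{truncated_normal}{normal density with mean \code{Rmp} and width
#'     \code{sigma}, restricted to R >= 0 and renormalized; the common
#'     large-distance approximation, which overweights small distances.}
#'   \item{gaussian_chain}{the central (Rmp = 0) chi distribution, i.e. the
#'     Maxwell form ~ R^2 exp(-R^2 / 2 sigma^2); end-to-end distance of an
#'     ideal polymer with \code{<R^2> = 3 sigma^2}.}
#'   \item{wlc}{worm-like chain of contour length \code{L} and stiffness
#'     \code{kappa} = persistence length / L (mean-field interpolation
#'     radial density, normalized numerically on [0, L)).}
#'   \item{mixture}{weighted sum of component distributions; moments are
#'     combined linearly per component.}
#' }
#'
#' @param family one of \code{"chi"}, \code{"truncated_normal"},
#'   \code{"gaussian_chain"}, \code{"wlc"}, \code{"mixture"}.
#' @param Rmp mean-position distance in Angstrom (chi, truncated_normal).
#' @param sigma width parameter in Angstrom (chi, truncated_normal,
#'   gaussian_chain).
#' @param L contour length in Angstrom (wlc).
#' @param kappa stiffness = persistence length / contour length (wlc).
#' @param components list of \code{distance_distribution} objects (mixture).
#' @param weights mixture weights summing to 1.
#' @return An object of class \code{"distance_distribution"}.
#' @examples
#' chi <- distance_distribution("chi", Rmp = 50, sigma = 6)
#' wlc <- distance_distribution("wlc", L = 120, kappa = 0.3)
#' @export
distance_distribution <- function(family = c("chi", "truncated_normal",
                                             "gaussian_chain", "wlc",
                                             "mixture"),
                                  Rmp = NULL, sigma = NULL, L = NULL,
                                  kappa = NULL, components = NULL,
                                  weights = NULL) {
  family <- match.arg(family)
  d <- switch(family,
    chi = {
      stopifnot(sigma > 0, Rmp >= 0)
      list(Rmp = Rmp, sigma = sigma)
    },
    truncated_normal = {
      stopifnot(sigma > 0)
      list(Rmp = Rmp, sigma = sigma)
    },
    gaussian_chain = {
      stopifnot(sigma > 0)
      list(sigma = sigma)
    },
    wlc = {
      stopifnot(L > 0, kappa > 0)
      list(L = L, kappa = kappa, logZ = wlc_log_norm(L, kappa))
    },
    mixture = {
      stopifnot(is.list(components), length(components) == length(weights),
                all(vapply(components, inherits, logical(1),
                           "distance_distribution")))
      if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
        stop("mixture weights must be non-negative and sum to 1")
      list(components = components, weights = as.numeric(weights))
    })
  structure(c(list(family = family), d), class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("Distance distribution:", x$family, "\n")
  p <- x[setdiff(names(x), c("family", "components", "logZ"))]
  if (length(p)) cat(" ", paste(names(p), unlist(lapply(p, format)),
                                sep = " = ", collapse = ", "), "\n")
  if (x$family == "mixture")
    cat(sprintf("  %d components\n", length(x$components)))
  invisible(x)
}

#' Non-central chi distance density
#'
#' Density of the distance between two points whose positions are
#' isotropic normals separated by \code{Rmp}:
#' (R/Rmp) [N(R | Rmp, sigma) - N(R | -Rmp, sigma)] for Rmp > 0, with the
#' continuous Maxwell limit at Rmp = 0. Tends to the normal density when
#' sigma/Rmp -> 0.
#'
#' @param R distance(s) in Angstrom (vectorized).
#' @param Rmp mean-position distance, >= 0.
#' @param sigma per-axis width, > 0.
#' @return Density in 1/Angstrom (0 for R < 0).
#' @export
chi_pdf <- function(R, Rmp, sigma) {
  stopifnot(sigma > 0, Rmp >= 0)
  out <- numeric(length(R))
  ok <- R >= 0
  r <- R[ok]
  if (Rmp < 1e-10 * sigma) {
    # central limit: Maxwell form, <R^2> = 3 sigma^2
    out[ok] <- sqrt(2 / pi) * r^2 / sigma^3 * exp(-r^2 / (2 * sigma^2))
  } else {
    out[ok] <- (r / Rmp) *
      (stats::dnorm(r, Rmp, sigma) - stats::dnorm(r, -Rmp, sigma))
  }
  out
}

#' Truncated normal distance density
#'
#' Normal density with mean \code{Rmp} and sd \code{sigma} restricted to
#' R >= 0 and renormalized to unit mass. For Rmp >> sigma the
#' renormalization factor is 1 to machine precision.
#'
#' @inheritParams chi_pdf
#' @return Density in 1/Angstrom (0 for R < 0).
#' @export
truncated_normal_pdf <- function(R, Rmp, sigma) {
  stopifnot(sigma > 0)
  mass <- stats::pnorm(0, Rmp, sigma, lower.tail = FALSE)
  out <- numeric(length(R))
  ok <- R >= 0
  out[ok] <- stats::dnorm(R[ok], Rmp, sigma) / mass
  out
}

#' Worm-like chain log normalization constant
#' @noRd
wlc_log_norm <- function(L, kappa) {
  f <- function(x) wlc_kernel(x, kappa)
  z <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                        subdivisions = 1000L)$value
  log(z) + log(L)   # density in R = L x needs 1/L Jacobian absorbed here
}

#' Unnormalized WLC radial kernel in x = R/L
#' @noRd
wlc_kernel <- function(x, kappa) {
  out <- numeric(length(x))
  ok <- x >= 0 & x < 1
  u <- 1 - x[ok]^2
  out[ok] <- x[ok]^2 * u^(-9 / 2) * exp(-3 / (4 * kappa * u))
  out
}

#' Worm-like chain distance density
#'
#' Mean-field interpolation for the radial end-to-end density of a
#' worm-like chain of contour length \code{L} and stiffness
#' \code{kappa} = l_p / L:
#' p(R) ~ R^2 (1 - (R/L)^2)^(-9/2) exp(-3 / (4 kappa (1 - (R/L)^2))),
#' normalized numerically on [0, L). The flexible limit (small kappa)
#' recovers ideal-chain statistics with <R^2> -> 2 kappa L^2; the stiff
#' limit concentrates near R = L (rigid rod).
#'
#' @param R distance(s) in Angstrom (vectorized); density is 0 for R >= L.
#' @param L contour length in Angstrom, > 0.
#' @param kappa stiffness (persistence length / L), > 0.
#' @return Density in 1/Angstrom.
#' @export
wlc_pdf <- function(R, L, kappa) {
  stopifnot(L > 0, kappa > 0)
  logZ <- wlc_log_norm(L, kappa)
  wlc_kernel(R / L, kappa) * exp(-logZ)
}

#' Evaluate a distance distribution density
#'
#' @param dist a [distance_distribution()].
#' @param R distance(s) in Angstrom.
#' @return Density values in 1/Angstrom.
#' @export
ddist_pdf <- function(dist, R) {
  stopifnot(inherits(dist, "distance_distribution"))
  switch(dist$family,
    chi = chi_pdf(R, dist$Rmp, dist$sigma),
    truncated_normal = truncated_normal_pdf(R, dist$Rmp, dist$sigma),
    gaussian_chain = chi_pdf(R, 0, dist$sigma),
    wlc = wlc_kernel(R / dist$L, dist$kappa) * exp(-dist$logZ),
    mixture = {
      Reduce(`+`, lapply(seq_along(dist$components), function(i)
        dist$weights[i] * ddist_pdf(dist$components[[i]], R)))
    })
}

#' Integration support of a distance distribution
#' @noRd
ddist_support <- function(dist) {
  switch(dist$family,
    chi = c(max(0, dist$Rmp - 10 * dist$sigma), dist$Rmp + 10 * dist$sigma),
    truncated_normal = c(max(0, dist$Rmp - 10 * dist$sigma),
                         dist$Rmp + 10 * dist$sigma),
    gaussian_chain = c(0, 10 * dist$sigma),
    wlc = c(0, dist$L),
    mixture = {
      s <- vapply(dist$components, ddist_support, numeric(2))
      c(min(s[1, ]), max(s[2, ]))
    })
}

#' Draw random distances from a distance distribution
#'
#' Sampling routes are exact per family: the chi and Gaussian-chain
#' families sample the underlying 3-D displacement vector, the truncated
#' normal uses rejection, the WLC uses inverse-CDF interpolation on a fine
#' grid, and mixtures sample a component first.
#'
#' @param n number of draws.
#' @param dist a [distance_distribution()].
#' @return Numeric vector of distances (Angstrom).
#' @export
sample_distance <- function(n, dist) {
  stopifnot(inherits(dist, "distance_distribution"))
  switch(dist$family,
    chi = sqrt((dist$Rmp + stats::rnorm(n, 0, dist$sigma))^2 +
               stats::rnorm(n, 0, dist$sigma)^2 +
               stats::rnorm(n, 0, dist$sigma)^2),
    gaussian_chain = sqrt(stats::rnorm(n, 0, dist$sigma)^2 +
                          stats::rnorm(n, 0, dist$sigma)^2 +
                          stats::rnorm(n, 0, dist$sigma)^2),
    truncated_normal = {
      out <- numeric(0)
      while (length(out) < n) {
        x <- stats::rnorm(2L * (n - length(out)), dist$Rmp, dist$sigma)
        out <- c(out, x[x >= 0])
      }
      out[seq_len(n)]
    },
    wlc = {
      x <- seq(0, 1 - 1e-9, length.out = 4096)
      pdf <- wlc_kernel(x, dist$kappa)
      cdf <- cumsum(pdf); cdf <- cdf / cdf[length(cdf)]
      dist$L * stats::approx(cdf, x, stats::runif(n), ties = "ordered",
                             yleft = 0, yright = 1)$y
    },
    mixture = {
      idx <- sample.int(length(dist$weights), n, replace = TRUE,
                        prob = dist$weights)
      out <- numeric(n)
      for (i in unique(idx))
        out[idx == i] <- sample_distance(sum(idx == i), dist$components[[i]])
      out
    })
}

#' Donor lifetime as a function of distance
#' @noRd
tau_of_R <- function(R, ctx) {
  R <- pmax(R, 1e-3)   # floor avoids 0/0 at the origin; density there ~ 0
  ctx$tau_D0 / (1 + (ctx$R0 / R)^6)
}

#' Lifetime moments of a distance distribution
#'
#' Numerical quadrature of tau(R)^nu p(R) over the support, with
#' tau(R) = tau_D0 / (1 + (R0/R)^6). The fast-linker (stationary
#' distribution) regime is assumed: distance fluctuations are slow
#' compared to the lifetime but fast compared to the observation time.
#' Mixture distributions are integrated per component and combined
#' linearly.
#'
#' @param dist a [distance_distribution()].
#' @param ctx a [fret_context()].
#' @param rel.tol relative quadrature tolerance.
#' @return A [moment_pair()].
#' @export
lifetime_moments_from_distribution <- function(dist, ctx, rel.tol = 1e-9) {
  ctx <- as_fret_context(ctx)
  stopifnot(inherits(dist, "distance_distribution"))
  if (dist$family == "mixture") {
    mom <- vapply(dist$components, function(cm) {
      m <- lifetime_moments_from_distribution(cm, ctx, rel.tol)
      c(m$m1, m$m2)
    }, numeric(2))
    return(moment_pair(sum(dist$weights * mom[1, ]),
                       sum(dist$weights * mom[2, ])))
  }
  sup <- ddist_support(dist)
  q <- function(nu) {
    r <- tryCatch(
      stats::integrate(function(R) ddist_pdf(dist, R) * tau_of_R(R, ctx)^nu,
                       sup[1], sup[2], rel.tol = rel.tol, abs.tol = 0,
                       subdivisions = 400L),
      error = function(e)
        stop("lifetime-moment quadrature failed for family '", dist$family,
             "': ", conditionMessage(e)))
    r$value
  }
  moment_pair(q(1), q(2))
}

#' A conformational state with linker-averaged moments
#'
#' The linker-averaged first and second lifetime moments of one
#' conformational state, obtained either by quadrature over a distance
#' model or directly from the measured observables (E, tauF) of the pure
#' state -- the two routes agree when the observables were generated by
#' the model.
#'
#' @param s a [fret_state()]; if it has a \code{distance_model} the
#'   moments come from quadrature, otherwise from its fixed-dye lifetime.
#' @param ctx a [fret_context()].
#' @param observables optional list with \code{E}, \code{tauF}: when given,
#'   moments are taken from the observables instead of any model.
#' @return An object of class \code{"linker_averaged_state"} with fields
#'   \code{label} and \code{moments} (a [moment_pair()]).
#' @export
linker_averaged_state <- function(s, ctx, observables = NULL) {
  ctx <- as_fret_context(ctx)
  m <- if (!is.null(observables)) {
    observables_to_moments(observables, ctx)
  } else if (inherits(s, "fret_state") && !is.null(s$distance_model)) {
    lifetime_moments_from_distribution(s$distance_model, ctx)
  } else if (inherits(s, "fret_state")) {
    tau <- state_lifetime(s, ctx)
    moment_pair(tau, tau^2)
  } else {
    stop("provide a fret_state or observables")
  }
  structure(list(label = if (inherits(s, "fret_state")) s$label else "state",
                 moments = m),
            class = "linker_averaged_state")
}

#' Linker-corrected static FRET-line
#'
#' Sweeps the mean-position distance Rmp at fixed linker width sigma,
#' computing the lifetime moments of the chi (or truncated-normal)
#' distance distribution at each point. The finite distribution width
#' shifts every sample toward longer tauF relative to the ideal static
#' line; sigma = 0 reproduces the ideal line.
#'
#' @param ctx a [fret_context()].
#' @param sigma linker width sigma_DA in Angstrom (>= 0); 6 Angstrom is a
#'   typical value for common dye linkers.
#' @param family \code{"chi"} or \code{"truncated_normal"}.
#' @param Rmp_grid mean-position distances to sweep (Angstrom, increasing).
#' @return A [fret_line()] of kind \code{"static_linker"} parameterized by
#'   Rmp.
#' @export
static_line_linker <- function(ctx, sigma = 6,
                               family = c("chi", "truncated_normal"),
                               Rmp_grid = NULL) {
  ctx <- as_fret_context(ctx)
  family <- match.arg(family)
  stopifnot(sigma >= 0)
  if (is.null(Rmp_grid))
    Rmp_grid <- seq(0.2 * ctx$R0, 3 * ctx$R0, length.out = 101)
  if (sigma == 0) {
    tau <- tau_of_R(Rmp_grid, ctx)
    return(fret_line(samples_from_moments(Rmp_grid, tau, tau^2, ctx),
                     "static_linker", "Rmp", ctx,
                     model = list(sigma = 0, family = family)))
  }
  mom <- vapply(Rmp_grid, function(Rmp) {
    d <- distance_distribution(family, Rmp = Rmp, sigma = sigma)
    m <- lifetime_moments_from_distribution(d, ctx)
    c(m$m1, m$m2)
  }, numeric(2))
  fret_line(samples_from_moments(Rmp_grid, mom[1, ], mom[2, ], ctx),
            "static_linker", "Rmp", ctx,
            model = list(sigma = sigma, family = family))
}

#' Dynamic FRET-line between linker-broadened states
#'
#' Mixes the linker-averaged moments of two conformational states linearly
#' in the occupancy fraction x1. Because linker and conformational
#' timescales separate, this equals the moments of the full two-component
#' mixture distance distribution, and the line stays straight in the
#' moment representation; the endpoints are the linker-shifted pure-state
#' coordinates.
#'
#' @param s1,s2 [linker_averaged_state()] objects (or [fret_state()]s,
#'   which are converted via the context).
#' @param ctx a [fret_context()].
#' @param n_points samples, uniform in x1.
#' @return A [fret_line()] of kind \code{"dynamic"}.
#' @export
dynamic_line_with_linkers <- function(s1, s2, ctx, n_points = 201) {
  ctx <- as_fret_context(ctx)
  las <- lapply(list(s1, s2), function(s) {
    if (inherits(s, "linker_averaged_state")) s
    else linker_averaged_state(s, ctx)
  })
  m1s <- vapply(las, function(s) s$moments$m1, numeric(1))
  m2s <- vapply(las, function(s) s$moments$m2, numeric(1))
  x1 <- seq(1, 0, length.out = n_points)
  m1 <- x1 * m1s[1] + (1 - x1) * m1s[2]
  m2 <- x1 * m2s[1] + (1 - x1) * m2s[2]
  fret_line(samples_from_moments(x1, m1, m2, ctx), "dynamic", "x1", ctx,
            model = list(state_moments = list(m1 = m1s, m2 = m2s)))
}

#' Conformational / linker variance decomposition
#'
#' Splits the total lifetime variance of a multi-state mixture with
#' linker-broadened states into the between-state variance of the
#' linker-averaged mean lifetimes and the fraction-weighted mean of the
#' within-state linker variances. The two contributions are exactly
#' additive.
#'
#' @param states list of [linker_averaged_state()] objects.
#' @param fractions occupancy fractions summing to 1.
#' @return List with \code{total}, \code{conformational}, \code{linker}
#'   variances (ns^2).
#' @export
variance_decomposition <- function(states, fractions) {
  stopifnot(length(states) == length(fractions),
            all(vapply(states, inherits, logical(1),
                       "linker_averaged_state")))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  m1s <- vapply(states, function(s) s$moments$m1, numeric(1))
  m2s <- vapply(states, function(s) s$moments$m2, numeric(1))
  m1 <- sum(fractions * m1s)
  m2 <- sum(fractions * m2s)
  conf <- sum(fractions * (m1s - m1)^2)
  linker <- sum(fractions * (m2s - m1s^2))
  list(total = m2 - m1^2, conformational = conf, linker = linker)
}

#' Polymer FRET-lines (Gaussian chain and worm-like chain)
#'
#' Reference lines for disordered chains:
#' \describe{
#'   \item{gc_sweep_sigma}{the single Gaussian-chain line, swept over the
#'     width sigma (equivalently the mean-squared distance 3 sigma^2).}
#'   \item{wlc_sweep_kappa_fixed_L}{WLC line at fixed contour length L,
#'     swept over stiffness kappa.}
#'   \item{wlc_sweep_L_fixed_kappa}{WLC line at fixed kappa, swept over L.}
#' }
#' Different (kappa, L) combinations can give identical efficiencies but
#' different tauF, which is what makes the two-dimensional representation
#' informative for disordered systems.
#'
#' @param ctx a [fret_context()].
#' @param mode sweep mode, see Description.
#' @param grid values of the swept parameter (sigma in Angstrom, kappa, or
#'   L in Angstrom).
#' @param L contour length (Angstrom), for \code{wlc_sweep_kappa_fixed_L}.
#' @param kappa stiffness, for \code{wlc_sweep_L_fixed_kappa}.
#' @return A [fret_line()] of kind \code{"gaussian_chain"} or \code{"wlc"}.
#' @export
polymer_lines <- function(ctx, mode = c("gc_sweep_sigma",
                                        "wlc_sweep_kappa_fixed_L",
                                        "wlc_sweep_L_fixed_kappa"),
                          grid = NULL, L = NULL, kappa = NULL) {
  ctx <- as_fret_context(ctx)
  mode <- match.arg(mode)
  if (mode == "gc_sweep_sigma") {
    if (is.null(grid))
      grid <- exp(seq(log(0.05 * ctx$R0), log(3 * ctx$R0), length.out = 101))
    mom <- vapply(grid, function(s) {
      d <- distance_distribution("gaussian_chain", sigma = s)
      m <- lifetime_moments_from_distribution(d, ctx)
      c(m$m1, m$m2)
    }, numeric(2))
    return(fret_line(samples_from_moments(grid, mom[1, ], mom[2, ], ctx),
                     "gaussian_chain", "sigma", ctx))
  }
  if (mode == "wlc_sweep_kappa_fixed_L") {
    stopifnot(!is.null(L))
    if (is.null(grid)) grid <- exp(seq(log(0.02), log(20), length.out = 61))
    mom <- vapply(grid, function(k) {
      d <- distance_distribution("wlc", L = L, kappa = k)
      m <- lifetime_moments_from_distribution(d, ctx)
      c(m$m1, m$m2)
    }, numeric(2))
    return(fret_line(samples_from_moments(grid, mom[1, ], mom[2, ], ctx),
                     "wlc", "kappa", ctx, model = list(L = L)))
  }
  stopifnot(!is.null(kappa))
  if (is.null(grid)) grid <- seq(0.4 * ctx$R0, 4 * ctx$R0, length.out = 61)
  mom <- vapply(grid, function(l) {
    d <- distance_distribution("wlc", L = l, kappa = kappa)
    m <- lifetime_moments_from_distribution(d, ctx)
    c(m$m1, m$m2)
  }, numeric(2))
  fret_line(samples_from_moments(grid, mom[1, ], mom[2, ], ctx),
            "wlc", "L", ctx, model = list(kappa = kappa))
}

#' Order-disorder (folding) FRET-line
#'
#' Exchange between a folded state with a linker distance distribution
#' (typically chi) and an unfolded state described by a polymer model
#' (typically WLC): the combined distance distribution is the x_f-weighted
#' mixture, and sweeping the folded fraction x_f from 0 to 1 traces the
#' folding line. The component moments mix linearly, so the line is
#' straight in the moment representation.
#'
#' @param folded a [distance_distribution()] for the folded state.
#' @param unfolded a [distance_distribution()] for the unfolded state.
#' @param ctx a [fret_context()].
#' @param n_points samples, uniform in x_f.
#' @return A [fret_line()] of kind \code{"order_disorder"} parameterized by
#'   the folded fraction \code{xf} (running 0 at the unfolded end to 1).
#' @export
order_disorder_line <- function(folded, unfolded, ctx, n_points = 201) {
  ctx <- as_fret_context(ctx)
  mf <- lifetime_moments_from_distribution(folded, ctx)
  mu <- lifetime_moments_from_distribution(unfolded, ctx)
  xf <- seq(0, 1, length.out = n_points)
  m1 <- xf * mf$m1 + (1 - xf) * mu$m1
  m2 <- xf * mf$m2 + (1 - xf) * mu$m2
  fret_line(samples_from_moments(xf, m1, m2, ctx), "order_disorder", "xf",
            ctx, model = list(folded = folded, unfolded = unfolded))
}

#' Export a distance distribution as a two-column table
#'
#' @param dist a [distance_distribution()].
#' @param file path to write (comma-separated, columns \code{R_A},
#'   \code{density}); \code{NULL} returns the data.frame.
#' @param n number of grid points over the support.
#' @return The data.frame, invisibly when written to file.
#' @export
export_distance_distribution <- function(dist, file = NULL, n = 512) {
  sup <- ddist_support(dist)
  R <- seq(sup[1], sup[2], length.out = n)
  df <- data.frame(R_A = R, density = ddist_pdf(dist, R))
  if (is.null(file)) return(df)
  utils::write.csv(format(df, digits = 17, scientific = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}
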