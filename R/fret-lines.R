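#' A conformational state of a FRET construct
#'
#' One conformational state, specified either by its FRET efficiency
#' \code{E} or by the distance between the dye mean positions \code{Rmp}
#' (Angstrom); exactly one of the two is the primary specification.
#' A state may additionally carry a distance-distribution model (see
#' [distance_distribution()]) describing linker or polymer broadening.
#'
#' @param label short state name.
#' @param E FRET efficiency in [0, 1], or \code{NULL}.
#' @param Rmp mean-position inter-dye distance in Angstrom, or \code{NULL}.
#' @param distance_model optional [distance_distribution()].
#' @return An object of class \code{"fret_state"}.
#' @export
fret_state <- function(label = "state", E = NULL, Rmp = NULL,
                       distance_model = NULL) {
  if (is.null(E) == is.null(Rmp))
    stop("specify exactly one of 'E' or 'Rmp'")
  if (!is.null(E) && (E < 0 || E > 1)) stop("'E' must lie in [0, 1]")
  if (!is.null(Rmp) && Rmp < 0) stop("'Rmp' must be non-negative")
  if (!is.null(distance_model) &&
      !inherits(distance_model, "distance_distribution"))
    stop("'distance_model' must be a distance_distribution")
  structure(list(label = label, E = E, Rmp = Rmp,
                 distance_model = distance_model),
            class = "fret_state")
}

#' State efficiency resolved against a context
#' @noRd
state_efficiency <- function(s, ctx) {
  if (!is.null(s$E)) s$E else efficiency_from_distance(s$Rmp, ctx)
}

#' State lifetime resolved against a context (fixed-dye, no linker model)
#' @noRd
state_lifetime <- function(s, ctx) {
  lifetime_from_efficiency(state_efficiency(s, ctx), ctx)
}

# --- LineCurve container ----------------------------------------------------

line_kinds <- c("static_ideal", "static_linker", "dynamic", "gaussian_chain",
                "wlc", "order_disorder", "static_PR_slow", "static_PR_fast",
                "dynamic_mean_variance")

#' Construct a FRET-line curve object
#'
#' Internal constructor for the ordered-sample container used by every line
#' generator. Samples carry the line's natural parameter, the observables
#' (E, tauF), the moment difference Gamma and the raw moments; each sample
#' must satisfy the transform consistency Gamma = (1 - E)(1 - tauF/tau_norm)
#' within 1e-9, where tau_norm is the normalization lifetime recorded in the
#' metadata (tau_D0, or the intensity-weighted donor-only lifetime for donor
#' mixtures).
#'
#' @param samples data.frame with columns \code{param}, \code{E},
#'   \code{tauF_ns}, \code{Gamma}, \code{m1_ns}, \code{m2_ns2}.
#' @param kind one of the supported line kinds.
#' @param param_name name of the varying parameter.
#' @param ctx the [fret_context()] used.
#' @param model list of model parameters (recorded as metadata).
#' @param tau_norm normalization lifetime used for Gamma (defaults to
#'   \code{ctx$tau_D0}).
#' @return An object of classes \code{"fret_line"} and \code{"data.frame"}.
#' @keywords internal
#' @export
fret_line <- function(samples, kind, param_name, ctx, model = list(),
                      tau_norm = ctx$tau_D0) {
  kind <- match.arg(kind, line_kinds)
  need <- c("param", "E", "tauF_ns", "Gamma", "m1_ns", "m2_ns2")
  if (kind != "dynamic_mean_variance") {
    stopifnot(all(need %in% names(samples)))
    if (is.unsorted(samples$param) && is.unsorted(rev(samples$param)))
      stop("samples must be ordered by the line parameter")
    resid <- samples$Gamma -
      (1 - samples$E) * (1 - samples$tauF_ns / tau_norm)
    if (any(abs(resid) > 1e-9))
      stop("internal error: Gamma transform inconsistency in line samples")
  }
  structure(samples,
            class = c("fret_line", "data.frame"),
            kind = kind, param_name = param_name,
            context = ctx, model = model, tau_norm = tau_norm)
}

#' @export
print.fret_line <- function(x, ...) {
  cat(sprintf("FRET-line (%s), %d samples, parameter '%s'\n",
              attr(x, "kind"), nrow(x), attr(x, "param_name")))
  ctx <- attr(x, "context")
  cat(sprintf("  R0 = %g A, tau_D0 = %g ns, Gamma normalized by %g ns\n",
              ctx$R0, ctx$tau_D0, attr(x, "tau_norm")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Plot a FRET-line
#'
#' Draws the curve in the (tauF, E) plane or in the moment representation
#' (E, Gamma). The ideal static line (diagonal, or parabola) is overlaid for
#' reference.
#'
#' @param x a \code{fret_line}.
#' @param representation \code{"E_tauF"} or \code{"moment"}.
#' @param add add to an existing plot.
#' @param ... passed to [graphics::lines()].
#' @export
plot.fret_line <- function(x, representation = c("E_tauF", "moment"),
                           add = FALSE, ...) {
  representation <- match.arg(representation)
  ctx <- attr(x, "context")
  if (representation == "E_tauF") {
    if (!add) {
      graphics::plot(NA, xlim = c(0, ctx$tau_D0 * 1.05), ylim = c(0, 1),
                     xlab = expression(tau[F] ~ "(ns)"), ylab = "E")
      graphics::abline(a = 1, b = -1 / ctx$tau_D0, col = "grey50")
    }
    graphics::lines(x$tauF_ns, x$E, ...)
  } else {
    if (!add) {
      e <- seq(0, 1, length.out = 201)
      graphics::plot(e, (1 - e) * e, type = "l", col = "grey50",
                     xlab = "E", ylab = expression(Gamma))
    }
    graphics::lines(x$E, x$Gamma, ...)
  }
  invisible(x)
}

#' Assemble line samples from moments
#' @noRd
samples_from_moments <- function(param, m1, m2, ctx, tau_norm = ctx$tau_D0,
                                 E = NULL) {
  if (is.null(E)) E <- 1 - m1 / ctx$tau_D0
  tauF <- ifelse(m1 > 1e-12, m2 / m1, 0)
  data.frame(param = param, E = E, tauF_ns = tauF,
             Gamma = (1 - E) * (1 - tauF / tau_norm),
             m1_ns = m1, m2_ns2 = m2)
}

# --- Line generators --------------------------------------------------------

#' Ideal static FRET-line
#'
#' The locus of species with a single fluorescence lifetime:
#' E = 1 - tauF/tau_D0, a diagonal in the (tauF, E) plane and the parabola
#' Gamma = (1 - E) E in the moment representation.
#'
#' @param ctx a [fret_context()].
#' @param n_points number of samples (uniform in E), >= 2.
#' @return A [fret_line()] of kind \code{"static_ideal"}.
#' @examples
#' sl <- static_line_ideal(fret_context(50, 4))
#' @export
static_line_ideal <- function(ctx, n_points = 201) {
  ctx <- as_fret_context(ctx)
  stopifnot(n_points >= 2)
  E <- seq(0, 1, length.out = n_points)
  m1 <- (1 - E) * ctx$tau_D0
  fret_line(samples_from_moments(E, m1, m1^2, ctx, E = E),
            "static_ideal", "E", ctx)
}

#' Two-state dynamic FRET-line
#'
#' The curve traced in (tauF, E) by a molecule exchanging between two
#' fixed-dye states with lifetimes tau1, tau2, as the occupancy fraction
#' x1 of state 1 runs over [0, 1]:
#' E = 1 - (1/tau_D0) tau1 tau2 / (tau1 + tau2 - tauF).
#' Both endpoints lie on the static line; in the moment representation the
#' line is straight, Gamma = (1 - E1 - E2) E + E1 E2.
#'
#' @param s1,s2 [fret_state()] objects without distance models.
#' @param ctx a [fret_context()].
#' @param n_points samples, uniform in x1.
#' @return A [fret_line()] of kind \code{"dynamic"} parameterized by x1.
#' @export
dynamic_line_two_state <- function(s1, s2, ctx, n_points = 201) {
  ctx <- as_fret_context(ctx)
  stopifnot(inherits(s1, "fret_state"), inherits(s2, "fret_state"))
  if (!is.null(s1$distance_model) || !is.null(s2$distance_model))
    stop("use dynamic_line_with_linkers() for states with distance models")
  tau1 <- state_lifetime(s1, ctx); tau2 <- state_lifetime(s2, ctx)
  if (isTRUE(all.equal(tau1, tau2)))
    warning("identical states: dynamic line degenerates to a point")
  x1 <- seq(1, 0, length.out = n_points)  # param runs state1 -> state2
  m1 <- x1 * tau1 + (1 - x1) * tau2
  m2 <- x1 * tau1^2 + (1 - x1) * tau2^2
  fret_line(samples_from_moments(x1, m1, m2, ctx), "dynamic", "x1", ctx,
            model = list(tau1 = tau1, tau2 = tau2,
                         E1 = state_efficiency(s1, ctx),
                         E2 = state_efficiency(s2, ctx)))
}

#' Dynamic shift of a two-state system
#'
#' Maximum orthogonal distance between the two-state dynamic FRET-line and
#' the ideal static line, in the plane of E versus the normalized lifetime
#' tauF/tau_D0. Closed form: ds = (1/sqrt(2)) (sqrt(1-E1) - sqrt(1-E2))^2,
#' symmetric in the two efficiencies. The shift is a model-free indicator of
#' dynamics: it depends only on the limiting-state efficiencies, not on the
#' exchange rates.
#'
#' @param E1,E2 limiting-state FRET efficiencies in [0, 1].
#' @param method \code{"closed_form"} (default) or \code{"numeric"}
#'   (brute-force maximization of the point-to-line distance over a dense
#'   sampling of the dynamic line; independent cross-check).
#' @param n_grid grid size for the numeric method.
#' @return Dimensionless dynamic shift.
#' @examples
#' dynamic_shift(0.1, 0.9)   # 0.28 to two decimals
#' @export
dynamic_shift <- function(E1, E2, method = c("closed_form", "numeric"),
                          n_grid = 20001) {
  method <- match.arg(method)
  stopifnot(E1 >= 0, E1 <= 1, E2 >= 0, E2 <= 1)
  if (method == "closed_form")
    return((sqrt(1 - E1) - sqrt(1 - E2))^2 / sqrt(2))
  # numeric route: sample the dynamic line in normalized coordinates and
  # maximize the orthogonal distance to E = 1 - tauF/tauD0
  x1 <- seq(0, 1, length.out = n_grid)
  t1 <- 1 - E1; t2 <- 1 - E2      # tau/tauD0 of the pure states
  m1 <- x1 * t1 + (1 - x1) * t2
  m2 <- x1 * t1^2 + (1 - x1) * t2^2
  E <- 1 - m1
  tauFn <- ifelse(m1 > 0, m2 / m1, 0)
  max(abs(E - (1 - tauFn)) / sqrt(2))
}

#' FRET-line of a generic parameterized lifetime distribution
#'
#' The engine behind every specialized generator: for each value of the
#' varying parameter lambda, compute the first two moments of the lifetime
#' distribution p(tau | lambda) and map them to the observables
#' E = 1 - m1/tau_D0 and tauF = m2/m1.
#'
#' @param family a function \code{family(lambda)} returning either a
#'   [lifetime_mixture()] (discrete case) or a list
#'   \code{list(pdf = function(tau) ..., lower =, upper =)} describing a
#'   continuous density on tau >= 0 (checked to normalize to 1 within 1e-6).
#' @param lambda_grid ordered values of the varying parameter.
#' @param ctx a [fret_context()].
#' @param kind line kind recorded in the result.
#' @param param_name parameter name recorded in the result.
#' @return A [fret_line()].
#' @export
line_from_lifetime_distribution <- function(family, lambda_grid, ctx,
                                            kind = "dynamic",
                                            param_name = "lambda") {
  ctx <- as_fret_context(ctx)
  mom <- vapply(lambda_grid, function(l) {
    p <- family(l)
    if (inherits(p, "lifetime_mixture")) {
      m <- mixture_moments(p)
      c(m$m1, m$m2)
    } else {
      mass <- stats::integrate(p$pdf, p$lower, p$upper,
                               rel.tol = 1e-9, abs.tol = 0)$value
      if (abs(mass - 1) > 1e-6)
        stop(sprintf("lifetime density not normalized (mass %.8g)", mass))
      m1 <- stats::integrate(function(t) t * p$pdf(t), p$lower, p$upper,
                             rel.tol = 1e-9, abs.tol = 0)$value
      m2 <- stats::integrate(function(t) t^2 * p$pdf(t), p$lower, p$upper,
                             rel.tol = 1e-9, abs.tol = 0)$value
      c(m1, m2)
    }
  }, numeric(2))
  fret_line(samples_from_moments(lambda_grid, mom[1, ], mom[2, ], ctx),
            kind, param_name, ctx)
}

#' Limiting FRET-lines of a three-state system
#'
#' For three fixed-dye states, returns the three pairwise two-state dynamic
#' lines plus the three special limiting lines along which one species
#' fraction varies while the other two stay equal,
#' x_j = x_k = (1 - x_i)/2. The special lines all pass through the
#' equal-mixture point x1 = x2 = x3 = 1/3; in the moment representation all
#' mixtures lie inside the triangle spanned by the pure-state points.
#'
#' @param states list of three [fret_state()] objects.
#' @param ctx a [fret_context()].
#' @param n_points samples per line.
#' @return List with elements \code{pairwise} (3 lines, orders 1-2, 1-3,
#'   2-3) and \code{special} (3 lines, varying x1, x2, x3).
#' @export
limiting_lines_three_state <- function(states, ctx, n_points = 201) {
  ctx <- as_fret_context(ctx)
  stopifnot(length(states) == 3L)
  taus <- vapply(states, state_lifetime, numeric(1), ctx = ctx)
  if (anyDuplicated(signif(taus, 12)))
    warning("duplicate state lifetimes: lines are degenerate")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pairwise <- lapply(pairs, function(p)
    dynamic_line_two_state(states[[p[1]]], states[[p[2]]], ctx, n_points))
  special <- lapply(1:3, function(i) {
    xi <- seq(0, 1, length.out = n_points)
    frac <- rbind(xi, (1 - xi) / 2, (1 - xi) / 2)
    ord <- c(i, setdiff(1:3, i))       # row 1 is the varied species
    frac <- frac[order(ord), , drop = FALSE]
    m1 <- colSums(frac * taus)
    m2 <- colSums(frac * taus^2)
    fret_line(samples_from_moments(xi, m1, m2, ctx), "dynamic",
              paste0("x", i), ctx,
              model = list(taus = taus, varied = i))
  })
  list(pairwise = pairwise, special = special)
}

#' Species fractions from a point in the moment representation
#'
#' Inverts three-state mixing geometrically: both E and Gamma are linear in
#' the species fractions, so a mixture lies at the barycentric combination
#' of the three pure-state points in the (E, Gamma) plane. The fraction of
#' state i follows the segment-ratio construction: the line from vertex i
#' through the point meets the opposite edge at Q, and
#' x_i = |PQ| / (|PQ| + |vertex_i - P|).
#'
#' @param point numeric \code{c(E, Gamma)} coordinates of the population.
#' @param states list of three [fret_state()] objects.
#' @param ctx a [fret_context()].
#' @param tol how far (in barycentric units) outside the triangle a point
#'   may lie before an error is raised.
#' @return Named numeric vector \code{c(x1, x2, x3)} summing to 1. On an
#'   out-of-gamut error, the signed barycentric coordinates are reported in
#'   the error message.
#' @export
fractions_from_position <- function(point, states, ctx, tol = 1e-9) {
  ctx <- as_fret_context(ctx)
  stopifnot(length(states) == 3L, length(point) == 2L)
  taus <- vapply(states, state_lifetime, numeric(1), ctx = ctx)
  E_v <- 1 - taus / ctx$tau_D0
  G_v <- taus / ctx$tau_D0 - taus^2 / ctx$tau_D0^2
  V <- rbind(E_v, G_v)                       # 2 x 3 vertex matrix
  # signed barycentric coordinates by linear solve (also the oracle for the
  # segment construction below)
  A <- rbind(V, c(1, 1, 1))
  bary <- solve(A, c(point, 1))
  if (any(bary < -tol))
    stop(sprintf(paste0("point outside the three-state triangle; signed ",
                        "barycentric coordinates (%.6g, %.6g, %.6g)"),
                 bary[1], bary[2], bary[3]))
  # segment-ratio construction per vertex
  x <- vapply(1:3, function(i) {
    jk <- setdiff(1:3, i)
    vi <- V[, i]; vj <- V[, jk[1]]; vk <- V[, jk[2]]
    d <- point - vi; e <- vk - vj
    # intersect vi + t d with vj + s e
    M <- cbind(d, -e)
    if (abs(det(M)) < 1e-14) return(bary[i])  # point at vertex i: cevian undefined
    ts <- solve(M, vj - vi)
    Q <- vi + ts[1] * d
    a <- sqrt(sum((Q - point)^2))          # population -> opposite edge
    b <- sqrt(sum((point - vi)^2))         # vertex -> population
    if (a + b == 0) 1 else a / (a + b)
  }, numeric(1))
  x <- x / sum(x)
  names(x) <- paste0("x", 1:3)
  x
}

#' Two-state dynamic line in mean-variance coordinates
#'
#' The same two-state mixing expressed as the variance of the lifetime
#' distribution against its mean: Var(tau) = (taubar - tau1)(tau2 - taubar),
#' a downward parabola with zeros at the pure states and maximum
#' ((tau2 - tau1)/2)^2 at the midpoint. The FRET-efficiency variance is
#' Var(E) = Var(tau)/tau_D0^2.
#'
#' @param s1,s2 fixed-dye [fret_state()] objects.
#' @param ctx a [fret_context()].
#' @param n_points samples, uniform in x1.
#' @return A \code{fret_line} of kind \code{"dynamic_mean_variance"} with
#'   columns \code{param} (x1), \code{tau_mean_ns}, \code{var_ns2},
#'   \code{E}, \code{varE}.
#' @export
mean_variance_dynamic_line <- function(s1, s2, ctx, n_points = 201) {
  ctx <- as_fret_context(ctx)
  tau1 <- state_lifetime(s1, ctx); tau2 <- state_lifetime(s2, ctx)
  x1 <- seq(1, 0, length.out = n_points)
  m1 <- x1 * tau1 + (1 - x1) * tau2
  v <- (m1 - tau1) * (tau2 - m1)
  samples <- data.frame(param = x1, tau_mean_ns = m1, var_ns2 = v,
                        E = 1 - m1 / ctx$tau_D0, varE = v / ctx$tau_D0^2)
  fret_line(samples, "dynamic_mean_variance", "x1", ctx,
            model = list(tau1 = tau1, tau2 = tau2))
}
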