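#' Kinetic model of conformational exchange
#'
#' A continuous-time Markov model over conformational states. The rate
#' matrix holds the microscopic interconversion rates in 1/ms:
#' \code{rate_matrix[i, j]} is the rate from state j to state i
#' (off-diagonal); diagonals are defined internally as negative column
#' sums so that columns of the generator sum to zero.
#'
#' @param states list of [fret_state()] objects (fixed-dye: each resolves
#'   to one efficiency and one lifetime through the context).
#' @param rate_matrix square numeric matrix of off-diagonal rates (1/ms);
#'   the diagonal is ignored and recomputed.
#' @return An object of class \code{"kinetic_model"}.
#' @examples
#' m <- kinetic_model(
#'   list(fret_state("low", E = 0.25), fret_state("high", E = 0.8)),
#'   rate_matrix = matrix(c(0, 1, 1, 0), 2, 2))
#' equilibrium_distribution(m)
#' @export
kinetic_model <- function(states, rate_matrix) {
  stopifnot(is.list(states), length(states) >= 1L,
            all(vapply(states, inherits, logical(1), "fret_state")))
  n <- length(states)
  if (n == 1L) {
    rate_matrix <- matrix(0, 1, 1)
  } else {
    stopifnot(is.matrix(rate_matrix), nrow(rate_matrix) == n,
              ncol(rate_matrix) == n)
    if (any(rate_matrix[row(rate_matrix) != col(rate_matrix)] < 0))
      stop("off-diagonal rates must be non-negative")
  }
  diag(rate_matrix) <- 0
  diag(rate_matrix) <- -colSums(rate_matrix)
  structure(list(states = states, K = rate_matrix, n = n),
            class = "kinetic_model")
}

#' Equilibrium state occupancies
#'
#' Solves K pi = 0 with sum(pi) = 1 for the generator of a
#' [kinetic_model()]. The model must be irreducible (unique stationary
#' distribution).
#'
#' @param model a [kinetic_model()].
#' @return Numeric vector of equilibrium fractions.
#' @export
equilibrium_distribution <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  n <- model$n
  if (n == 1L) return(1)
  A <- rbind(model$K, rep(1, n))
  pi <- tryCatch(qr.solve(A, c(rep(0, n), 1)),
                 error = function(e) stop("rate matrix is singular"))
  if (any(pi < -1e-9))
    stop("rate matrix is reducible: no unique positive stationary ",
         "distribution")
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Simulation settings for synthetic bursts
#'
#' @param count_rate photon count rate per molecule in photons/ms
#'   (100 corresponds to the typical 100 kHz).
#' @param n_bursts number of bursts to keep after selection.
#' @param burst_duration \code{"exponential"} (mean = \code{diffusion_time},
#'   truncated at 10x the mean) or \code{"fixed"} (every burst lasts
#'   exactly \code{diffusion_time}).
#' @param diffusion_time mean burst duration in ms.
#' @param min_photons burst-selection threshold: bursts with fewer total
#'   photons are discarded (and counted).
#' @param seed integer root seed; mandatory for reproducibility. Each burst
#'   derives its own child stream from it, so burst b is identical
#'   regardless of \code{n_bursts}.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(count_rate = 100, n_bursts = 1000,
                       burst_duration = c("exponential", "fixed"),
                       diffusion_time = 0.5, min_photons = 50,
                       seed) {
  burst_duration <- match.arg(burst_duration)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer 'seed' is required")
  stopifnot(count_rate > 0, diffusion_time > 0, n_bursts >= 1,
            min_photons >= 0)
  structure(list(count_rate = count_rate, n_bursts = n_bursts,
                 burst_duration = burst_duration,
                 diffusion_time = diffusion_time,
                 min_photons = min_photons, seed = as.integer(seed)),
            class = "sim_config")
}

#' Child seed for one burst (kept below 2^31)
#' @noRd
burst_seed <- function(root, b) {
  (as.double(root) * 48271 + as.double(b) * 69621) %% 2147483399 + 1
}

#' Simulate a state trajectory (Gillespie path)
#'
#' Piecewise-constant conformational path over a fixed duration: the
#' initial state is drawn from the equilibrium distribution, dwell times
#' are exponential with the total exit rate of the current state, and
#' jumps choose the destination proportionally to the individual rates.
#'
#' @param model a [kinetic_model()].
#' @param duration path duration in ms.
#' @return data.frame with columns \code{state}, \code{t_start},
#'   \code{t_end} (ms).
#' @export
simulate_state_trajectory <- function(model, duration) {
  stopifnot(inherits(model, "kinetic_model"), duration > 0)
  pi <- equilibrium_distribution(model)
  s <- sample.int(model$n, 1, prob = pi)
  t <- 0
  states <- integer(0); starts <- numeric(0); ends <- numeric(0)
  repeat {
    exit <- -model$K[s, s]
    dwell <- if (exit > 0) stats::rexp(1, exit) else Inf
    t_end <- min(t + dwell, duration)
    states <- c(states, s); starts <- c(starts, t); ends <- c(ends, t_end)
    if (t_end >= duration) break
    rates <- model$K[, s]; rates[s] <- 0
    s <- sample.int(model$n, 1, prob = rates)
    t <- t_end
  }
  data.frame(state = states, t_start = starts, t_end = ends)
}

#' Simulate the photons of one burst
#'
#' Photon arrivals are a homogeneous Poisson process at the configured
#' count rate over the path duration (no diffusion-profile brightness
#' modulation). Each photon is assigned the state active at its arrival
#' time, becomes an acceptor photon with probability E(state), and donor
#' photons get an exponential TCSPC delay with mean tau_DA(state).
#' Acceptor delay times are not generated: the lifetime estimators in this
#' package use donor photons only.
#'
#' @param path trajectory from [simulate_state_trajectory()].
#' @param config a [sim_config()].
#' @param ctx a [fret_context()].
#' @param model the [kinetic_model()] the path came from.
#' @return data.frame with one row per photon: \code{macrotime_ms},
#'   \code{channel} ("D"/"A"), \code{delay_ns} (NA for acceptor photons),
#'   \code{state}.
#' @export
simulate_burst <- function(path, config, ctx, model) {
  ctx <- as_fret_context(ctx)
  duration <- path$t_end[nrow(path)]
  n <- stats::rpois(1, config$count_rate * duration)
  if (n == 0L)
    return(data.frame(macrotime_ms = numeric(0), channel = character(0),
                      delay_ns = numeric(0), state = integer(0)))
  t <- sort(stats::runif(n, 0, duration))
  st <- path$state[findInterval(t, path$t_start)]
  E <- vapply(model$states, state_efficiency, numeric(1), ctx = ctx)
  tau <- lifetime_from_efficiency(E, ctx)
  is_acc <- stats::runif(n) < E[st]
  delay <- rep(NA_real_, n)
  nd <- sum(!is_acc)
  if (nd > 0) {
    td <- tau[st[!is_acc]]
    if (any(td <= 0)) stop("state with E = 1 emits no donor photons")
    delay[!is_acc] <- stats::rexp(nd, rate = 1 / td)
  }
  data.frame(macrotime_ms = t, channel = ifelse(is_acc, "A", "D"),
             delay_ns = delay, state = st)
}

#' Simulate a burst experiment
#'
#' Generates bursts until \code{n_bursts} pass the minimum-photon
#' selection (bursts are attempted with independent child seed streams, so
#' the result is bit-identical for a fixed root seed regardless of how
#' many are requested). True state occupancies are recorded per burst for
#' oracle tests against the estimators.
#'
#' @param model a [kinetic_model()].
#' @param config a [sim_config()].
#' @param ctx a [fret_context()].
#' @param max_attempts_factor give up after
#'   \code{max_attempts_factor * n_bursts} attempted bursts.
#' @return An object of class \code{"burst_table"}: a list with
#'   \describe{
#'     \item{photons}{data.frame \code{burst_id}, \code{channel},
#'       \code{delay_ns}, \code{macrotime_ms}}
#'     \item{bursts}{per-burst summary: \code{burst_id}, \code{n_donor},
#'       \code{n_acceptor}, \code{duration_ms}, occupancy columns
#'       \code{occ_<k>}}
#'     \item{n_rejected}{bursts discarded by the photon threshold}
#'     \item{model}, \item{config}, \item{context}{inputs, recorded}
#'   }
#' @export
simulate_experiment <- function(model, config, ctx,
                                max_attempts_factor = 200) {
  stopifnot(inherits(model, "kinetic_model"), inherits(config, "sim_config"))
  ctx <- as_fret_context(ctx)
  kept <- 0L; attempt <- 0L; rejected <- 0L
  photons <- vector("list", config$n_bursts)
  summaries <- vector("list", config$n_bursts)
  max_attempts <- max_attempts_factor * config$n_bursts
  while (kept < config$n_bursts && attempt < max_attempts) {
    attempt <- attempt + 1L
    set.seed(burst_seed(config$seed, attempt))
    duration <- switch(config$burst_duration,
      fixed = config$diffusion_time,
      exponential = min(stats::rexp(1, 1 / config$diffusion_time),
                        10 * config$diffusion_time))
    path <- simulate_state_trajectory(model, duration)
    ph <- simulate_burst(path, config, ctx, model)
    if (nrow(ph) < config$min_photons) { rejected <- rejected + 1L; next }
    kept <- kept + 1L
    occ <- vapply(seq_len(model$n), function(k)
      sum((path$t_end - path$t_start)[path$state == k]) / duration,
      numeric(1))
    photons[[kept]] <- cbind(burst_id = kept,
                             ph[c("channel", "delay_ns", "macrotime_ms")])
    row <- data.frame(burst_id = kept,
                      n_donor = sum(ph$channel == "D"),
                      n_acceptor = sum(ph$channel == "A"),
                      duration_ms = duration)
    for (k in seq_len(model$n)) row[[paste0("occ_", k)]] <- occ[k]
    summaries[[kept]] <- row
  }
  if (kept < config$n_bursts)
    stop(sprintf("only %d of %d bursts passed selection after %d attempts",
                 kept, config$n_bursts, attempt))
  structure(list(photons = do.call(rbind, photons),
                 bursts = do.call(rbind, summaries),
                 n_rejected = rejected,
                 model = model, config = config, context = ctx),
            class = "burst_table")
}

#' @export
print.burst_table <- function(x, ...) {
  cat(sprintf("Burst table: %d bursts, %d photons (%d bursts rejected by the %d-photon threshold)\n",
              nrow(x$bursts), nrow(x$photons), x$n_rejected,
              x$config$min_photons))
  invisible(x)
}
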