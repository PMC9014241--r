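test_that("chi distance density normalizes and has the right limits", {
  expect_equal(integrate(chi_pdf, 0, 200, Rmp = 50, sigma = 7.5)$value, 1,
               tolerance = 1e-8)
  # central case: Maxwell form with <R^2> = 3 sigma^2
  R <- seq(0, 60, by = 0.5)
  expect_equal(chi_pdf(R, 0, 10),
               sqrt(2 / pi) * R^2 / 1000 * exp(-R^2 / 200), tolerance = 1e-12)
  r2 <- integrate(function(R) chi_pdf(R, 0, 10) * R^2, 0, 150)$value
  expect_equal(r2, 300, tolerance = 1e-6)
  # narrow-width limit tends to the normal density: the residual R/Rmp
  # prefactor makes the deviation scale like sigma/Rmp
  dev_at <- function(Rmp, sigma) {
    R <- seq(Rmp - 10 * sigma, Rmp + 10 * sigma, length.out = 2001)
    max(abs(chi_pdf(R, Rmp, sigma) - dnorm(R, Rmp, sigma)))
  }
  expect_lt(dev_at(100, 1), 3e-3)
  expect_lt(dev_at(1000, 1), 3e-4)
  expect_lt(dev_at(1000, 1), 0.2 * dev_at(100, 1))
  expect_equal(chi_pdf(-5, 50, 5), 0)
})

test_that("truncated normal density renormalizes its clipped mass", {
  expect_equal(integrate(truncated_normal_pdf, 0, Inf, Rmp = 15, sigma = 15,
                         rel.tol = 1e-12)$value, 1, tolerance = 1e-10)
  # far from the origin the truncation factor is 1
  expect_equal(truncated_normal_pdf(60, 60, 6), dnorm(60, 60, 6),
               tolerance = 1e-12)
  # overweights small distances relative to the chi model
  expect_gt(truncated_normal_pdf(5, 15, 15), chi_pdf(5, 15, 15))
})

test_that("worm-like chain density: normalization, rod and coil limits", {
  expect_equal(integrate(wlc_pdf, 0, 120, L = 120, kappa = 0.3)$value, 1,
               tolerance = 1e-6)
  expect_equal(wlc_pdf(130, 120, 0.3), 0)   # beyond the contour length
  # stiff chain concentrates near full extension
  mean_R <- integrate(function(R) wlc_pdf(R, 100, 10) * R, 0, 100)$value
  expect_gt(mean_R, 95)
  # flexible chain recovers ideal-chain statistics <R^2> ~ 2 kappa L^2
  r2 <- integrate(function(R) wlc_pdf(R, 100, 0.05) * R^2, 0, 100)$value
  expect_equal(r2, 2 * 0.05 * 100^2, tolerance = 0.15)
})

test_that("quadrature lifetime moments match Monte-Carlo sampling", {
  ctx <- ctx0
  set.seed(31)
  dists <- list(
    distance_distribution("chi", Rmp = 57.5, sigma = 7.5),
    distance_distribution("truncated_normal", Rmp = 45, sigma = 12),
    distance_distribution("gaussian_chain", sigma = 30),
    distance_distribution("wlc", L = 120, kappa = 0.3))
  for (d in dists) {
    m <- lifetime_moments_from_distribution(d, ctx)
    R <- sample_distance(2e5, d)
    tau <- 4 / (1 + (50 / pmax(R, 1e-3))^6)
    se1 <- sd(tau) / sqrt(length(tau))
    se2 <- sd(tau^2) / sqrt(length(tau))
    expect_lt(abs(m$m1 - mean(tau)), 3 * se1)
    expect_lt(abs(m$m2 - mean(tau^2)), 3 * se2)
  }
  # delta limit: sigma -> 0 at Rmp = R0 gives the E = 0.5 point
  dd <- distance_distribution("chi", Rmp = 50, sigma = 1e-5)
  md <- lifetime_moments_from_distribution(dd, ctx)
  expect_equal(md$m1, 2, tolerance = 1e-6)
})

test_that("linker-corrected static lines shift right, increasingly with sigma", {
  grid <- seq(30, 80, by = 5)
  l0 <- static_line_linker(ctx0, sigma = 0, Rmp_grid = grid)
  expect_equal(l0$E, 1 - l0$tauF_ns / 4, tolerance = 1e-6)
  l3 <- static_line_linker(ctx0, sigma = 3, Rmp_grid = grid)
  l6 <- static_line_linker(ctx0, sigma = 6, Rmp_grid = grid)
  # every broadened sample sits right of the ideal line
  expect_true(all(l6$tauF_ns > (1 - l6$E) * 4))
  expect_true(all(l3$tauF_ns > (1 - l3$E) * 4))
  # and monotonically so in sigma (compare at matched E by interpolation)
  for (E in seq(0.25, 0.75, by = 0.25)) {
    t3 <- approx(l3$E, l3$tauF_ns, E)$y
    t6 <- approx(l6$E, l6$tauF_ns, E)$y
    expect_gt(t6, t3)
  }
  # MC oracle at Rmp = 50
  set.seed(7)
  d50 <- distance_distribution("chi", Rmp = 50, sigma = 6)
  R <- sample_distance(2e5, d50)
  tau <- 4 / (1 + (50 / R)^6)
  i <- which(l6$param == 50)
  expect_lt(abs(l6$m1_ns[i] - mean(tau)), 3 * sd(tau) / sqrt(length(tau)))
})

test_that("chi and truncated-normal lines deviate most at large sigma, high E", {
  grid <- seq(25, 90, by = 5)
  dev_at <- function(sigma) {
    lc <- static_line_linker(ctx0, sigma, "chi", grid)
    ln <- static_line_linker(ctx0, sigma, "truncated_normal", grid)
    # compare E at matched tauF
    tf <- seq(max(min(lc$tauF_ns), min(ln$tauF_ns)) + 0.01,
              min(max(lc$tauF_ns), max(ln$tauF_ns)) - 0.01, length.out = 40)
    abs(approx(lc$tauF_ns, lc$E, tf)$y - approx(ln$tauF_ns, ln$E, tf)$y)
  }
  d5 <- dev_at(5); d20 <- dev_at(20)
  expect_lt(max(d5), max(d20))
})

test_that("linker-averaged states agree between model and observable routes", {
  s_fixed <- fret_state("f", E = 0.6)
  la <- linker_averaged_state(s_fixed, ctx0)
  expect_equal(la$moments$m1, 1.6)
  expect_equal(la$moments$m2, 1.6^2)
  d <- distance_distribution("chi", Rmp = 55, sigma = 7)
  s_mod <- fret_state("m", Rmp = 55, distance_model = d)
  la_mod <- linker_averaged_state(s_mod, ctx0)
  obs <- moments_to_observables(la_mod$moments, ctx0)
  la_obs <- linker_averaged_state(s_mod, ctx0, observables = obs)
  expect_equal(la_obs$moments$m1, la_mod$moments$m1, tolerance = 1e-9)
  expect_equal(la_obs$moments$m2, la_mod$moments$m2, tolerance = 1e-9)
  expect_gte(la_mod$moments$m2 - la_mod$moments$m1^2, 0)
})

test_that("dynamic lines between linker-broadened states mix moments linearly", {
  d1 <- distance_distribution("chi", Rmp = 57.5, sigma = 7.5)
  d2 <- distance_distribution("chi", Rmp = 34.5, sigma = 7.5)
  s1 <- fret_state("open", Rmp = 57.5, distance_model = d1)
  s2 <- fret_state("closed", Rmp = 34.5, distance_model = d2)
  dl <- dynamic_line_with_linkers(s1, s2, ctx0, 101)
  # endpoints are the linker-averaged pure states
  m1 <- lifetime_moments_from_distribution(d1, ctx0)
  m2 <- lifetime_moments_from_distribution(d2, ctx0)
  expect_equal(dl$m1_ns[1], m1$m1, tolerance = 1e-9)
  expect_equal(dl$m1_ns[nrow(dl)], m2$m1, tolerance = 1e-9)
  # endpoints sit right of the no-linker pure states
  tau_nolink <- 4 / (1 + (50 / c(57.5, 34.5))^6)
  expect_gt(dl$tauF_ns[1], tau_nolink[1])
  expect_gt(dl$tauF_ns[nrow(dl)], tau_nolink[2])
  # mid-fraction sample equals the quadrature of the mixed density
  dm <- distance_distribution("mixture", components = list(d1, d2),
                              weights = c(0.5, 0.5))
  mm <- lifetime_moments_from_distribution(dm, ctx0)
  mid <- dl[which.min(abs(dl$param - 0.5)), ]
  expect_equal(mid$m1_ns, mm$m1, tolerance = 1e-8)
  expect_equal(mid$m2_ns2, mm$m2, tolerance = 1e-8)
  # straight in the moment representation
  expect_lt(chord_residual(dl$E, dl$Gamma), 1e-9)
})

test_that("variance decomposes into conformational and linker parts", {
  # single state: everything is linker variance
  d <- distance_distribution("chi", Rmp = 50, sigma = 8)
  s <- linker_averaged_state(fret_state("s", Rmp = 50, distance_model = d),
                             ctx0)
  v1 <- variance_decomposition(list(s), 1)
  expect_equal(v1$conformational, 0)
  expect_equal(v1$total, v1$linker, tolerance = 1e-12)
  # zero-width linkers: two-state x(1-x)(tau1-tau2)^2
  sa <- linker_averaged_state(fret_state(E = 0.8), ctx0)
  sb <- linker_averaged_state(fret_state(E = 0.2), ctx0)
  v2 <- variance_decomposition(list(sa, sb), c(0.5, 0.5))
  expect_equal(v2$linker, 0, tolerance = 1e-12)
  expect_equal(v2$total, 0.25 * (3.2 - 0.8)^2, tolerance = 1e-12)
  # two chi-broadened states at x = 0.3 match direct quadrature
  d1 <- distance_distribution("chi", Rmp = 57.5, sigma = 7.5)
  d2 <- distance_distribution("chi", Rmp = 34.5, sigma = 6)
  s1 <- linker_averaged_state(fret_state(Rmp = 57.5, distance_model = d1), ctx0)
  s2 <- linker_averaged_state(fret_state(Rmp = 34.5, distance_model = d2), ctx0)
  v3 <- variance_decomposition(list(s1, s2), c(0.3, 0.7))
  dm <- distance_distribution("mixture", components = list(d1, d2),
                              weights = c(0.3, 0.7))
  mm <- lifetime_moments_from_distribution(dm, ctx0)
  expect_lt(abs(v3$total - (mm$m2 - mm$m1^2)), 1e-8)
  expect_lt(abs(v3$total - (v3$conformational + v3$linker)), 1e-10)
  # additivity on random mixtures
  set.seed(17)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    states <- lapply(1:n, function(j)
      linker_averaged_state(fret_state(E = runif(1, 0.05, 0.95)), ctx0))
    x <- runif(n); x <- x / sum(x)
    v <- variance_decomposition(states, x)
    expect_lt(abs(v$total - (v$conformational + v$linker)),
              1e-10 * max(v$total, 1))
  }
})

test_that("polymer lines cover the Gaussian-chain and WLC families", {
  gc <- polymer_lines(ctx0, "gc_sweep_sigma",
                      grid = exp(seq(log(2), log(200), length.out = 41)))
  # sigma -> 0: high-FRET corner; sigma -> large: donor-only corner
  expect_gt(gc$E[1], 0.99)
  expect_lt(gc$tauF_ns[1], 0.05)
  expect_lt(gc$E[nrow(gc)], 0.05)
  expect_gt(gc$tauF_ns[nrow(gc)], 3.8)
  # cross-check one point against Monte-Carlo at sigma = R0/sqrt(3)
  set.seed(13)
  sig <- 50 / sqrt(3)
  d <- distance_distribution("gaussian_chain", sigma = sig)
  R <- sample_distance(2e5, d)
  tau <- 4 / (1 + (50 / pmax(R, 1e-3))^6)
  m <- lifetime_moments_from_distribution(d, ctx0)
  expect_lt(abs(m$m1 - mean(tau)), 3 * sd(tau) / sqrt(length(tau)))
  # WLC: stiff limit approaches the fixed-distance static line
  wl_stiff <- polymer_lines(ctx0, "wlc_sweep_L_fixed_kappa", kappa = 100,
                            grid = seq(30, 90, by = 10))
  expect_lt(max(abs(wl_stiff$Gamma - (1 - wl_stiff$E) * wl_stiff$E)), 5e-3)
  # degenerate efficiencies at different (kappa, L) resolve in tauF
  wl1 <- polymer_lines(ctx0, "wlc_sweep_kappa_fixed_L", L = 80,
                       grid = c(0.05, 0.1, 0.3, 1, 3))
  wl2 <- polymer_lines(ctx0, "wlc_sweep_kappa_fixed_L", L = 140,
                       grid = c(0.05, 0.1, 0.3, 1, 3))
  E_common <- 0.5
  if (min(wl1$E) < E_common && max(wl1$E) > E_common &&
      min(wl2$E) < E_common && max(wl2$E) > E_common) {
    t1 <- approx(wl1$E, wl1$tauF_ns, E_common)$y
    t2 <- approx(wl2$E, wl2$tauF_ns, E_common)$y
    expect_gt(abs(t1 - t2), 1e-3)
  }
})

test_that("order-disorder line connects folded and unfolded endpoints linearly", {
  ctx52 <- fret_context(52, 4)
  folded <- distance_distribution("chi", Rmp = 52, sigma = 6)
  unfolded <- distance_distribution("wlc", L = 120, kappa = 0.3)
  od <- order_disorder_line(folded, unfolded, ctx52, 101)
  mf <- lifetime_moments_from_distribution(folded, ctx52)
  mu <- lifetime_moments_from_distribution(unfolded, ctx52)
  expect_equal(od$m1_ns[od$param == 1], mf$m1, tolerance = 1e-9)
  expect_equal(od$m1_ns[od$param == 0], mu$m1, tolerance = 1e-9)
  # midpoint equals quadrature of the mixed density
  dm <- distance_distribution("mixture", components = list(folded, unfolded),
                              weights = c(0.5, 0.5))
  mm <- lifetime_moments_from_distribution(dm, ctx52)
  mid <- od[which.min(abs(od$param - 0.5)), ]
  expect_equal(mid$m1_ns, mm$m1, tolerance = 1e-8)
  expect_equal(mid$m2_ns2, mm$m2, tolerance = 1e-8)
  expect_lt(chord_residual(od$E, od$Gamma), 1e-9)
})

test_that("densities export as two-column tables", {
  d <- distance_distribution("chi", Rmp = 50, sigma = 6)
  df <- export_distance_distribution(d, n = 256)
  expect_named(df, c("R_A", "density"))
  expect_true(all(df$density >= 0))
  f <- tempfile(fileext = ".csv")
  export_distance_distribution(d, f, n = 128)
  back <- read.csv(f)
  expect_equal(nrow(back), 128)
  unlink(f)
})
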