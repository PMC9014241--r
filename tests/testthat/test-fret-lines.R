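test_that("ideal static line: diagonal in (tauF, E), parabola in Gamma", {
  sl <- static_line_ideal(ctx0, 101)
  expect_equal(sl$E, 1 - sl$tauF_ns / 4)
  expect_equal(sl$tauF_ns[sl$E == 0], 4)
  expect_equal(sl$tauF_ns[sl$E == 1], 0)
  expect_equal(sl$tauF_ns[which.min(abs(sl$E - 0.5))], 2)
  expect_equal(sl$Gamma, (1 - sl$E) * sl$E)
  expect_equal(max(sl$Gamma), 0.25)
  expect_equal(sl$E[which.max(sl$Gamma)], 0.5)
})

test_that("two-state dynamic line connects the pure states through Eq-27", {
  s1 <- fret_state("hf", E = 0.8); s2 <- fret_state("lf", E = 0.2)
  dl <- dynamic_line_two_state(s1, s2, ctx0, 201)
  # endpoints on the static line at the pure states
  ends <- dl[c(1, nrow(dl)), ]
  expect_equal(ends$E, 1 - ends$tauF_ns / 4, tolerance = 1e-12)
  expect_equal(ends$E, c(0.8, 0.2))
  expect_true(all(dl$tauF_ns >= 0.8 - 1e-12 & dl$tauF_ns <= 3.2 + 1e-12))
  # the curve satisfies E = 1 - (1/tauD0) tau1 tau2 / (tau1 + tau2 - tauF)
  tau1 <- 0.8; tau2 <- 3.2
  expect_equal(dl$E, 1 - (tau1 * tau2 / (tau1 + tau2 - dl$tauF_ns)) / 4,
               tolerance = 1e-12)
  # moment-mixing oracle: at x = 0.5, tauF = 2.72 and E = 0.5
  mid <- dl[which.min(abs(dl$param - 0.5)), ]
  expect_equal(mid$tauF_ns, 2.72)
  expect_equal(mid$E, 0.5)
  # Gamma form (1 - E1 - E2) E + E1 E2 at E = 0.5
  expect_equal(mid$Gamma, (1 - 1.0) * 0.5 + 0.16)
  # straight in the moment representation
  expect_lt(chord_residual(dl$E, dl$Gamma), 1e-9)
  # swap invariance up to parameter reversal
  dl2 <- dynamic_line_two_state(s2, s1, ctx0, 201)
  expect_equal(rev(dl2$E), dl$E, tolerance = 1e-12)
  expect_equal(rev(dl2$tauF_ns), dl$tauF_ns, tolerance = 1e-12)
  expect_warning(dynamic_line_two_state(s1, fret_state("dup", E = 0.8), ctx0),
                 "degenerate")
})

test_that("every generated line passes the Gamma consistency check", {
  lines <- list(static_line_ideal(ctx0, 31),
                dynamic_line_two_state(fret_state(E = 0.1),
                                       fret_state(E = 0.9), ctx0, 31))
  for (ln in lines) {
    expect_lt(max(abs(ln$Gamma -
                      (1 - ln$E) * (1 - ln$tauF_ns / attr(ln, "tau_norm")))),
              1e-9)
  }
})

test_that("dynamic shift reproduces the worked two-state values", {
  expect_equal(round(dynamic_shift(0.1, 0.9), 2), 0.28)
  expect_equal(round(dynamic_shift(0.3, 0.7), 2), 0.06)
  expect_equal(round(dynamic_shift(0.5, 0.95), 2), 0.17)
  expect_equal(dynamic_shift(0.4, 0.4), 0)
  expect_equal(dynamic_shift(0.2, 0.7), dynamic_shift(0.7, 0.2))
})

test_that("closed-form dynamic shift agrees with brute-force maximization", {
  set.seed(8)
  for (i in 1:100) {
    E <- runif(2)
    expect_equal(dynamic_shift(E[1], E[2]),
                 dynamic_shift(E[1], E[2], method = "numeric"),
                 tolerance = 1e-6)
  }
})

test_that("the generic distribution engine reproduces specialized lines", {
  # two-delta family over x == dynamic line
  tau1 <- 0.8; tau2 <- 3.2
  fam <- function(x) lifetime_mixture(c(tau1, tau2), c(x, 1 - x))
  x <- seq(1, 0, length.out = 51)
  gen <- line_from_lifetime_distribution(fam, x, ctx0)
  dl <- dynamic_line_two_state(fret_state(E = 0.8), fret_state(E = 0.2),
                               ctx0, 51)
  expect_equal(gen$E, dl$E, tolerance = 1e-9)
  expect_equal(gen$tauF_ns, dl$tauF_ns, tolerance = 1e-9)
  # delta family == static line
  famd <- function(tau) lifetime_mixture(tau, 1)
  taus <- seq(4, 0.05, length.out = 21)
  gend <- line_from_lifetime_distribution(famd, taus, ctx0)
  expect_equal(gend$E, 1 - gend$tauF_ns / 4, tolerance = 1e-12)
  # three-component discrete family matches mixture_moments directly
  fam3 <- function(x) lifetime_mixture(c(0.5, 1.5, 3.5),
                                       c(x, (1 - x) / 2, (1 - x) / 2))
  g3 <- line_from_lifetime_distribution(fam3, 0.3, ctx0)
  m3 <- mixture_moments(fam3(0.3))
  expect_equal(g3$m1_ns, m3$m1)
  expect_equal(g3$m2_ns2, m3$m2)
  # continuous density: uniform lifetime distribution on [1, 3]
  famu <- function(width) list(pdf = function(t) dunif(t, 2 - width / 2,
                                                       2 + width / 2),
                               lower = 0, upper = 5)
  gu <- line_from_lifetime_distribution(famu, 2, ctx0)
  expect_equal(gu$m1_ns, 2, tolerance = 1e-8)
  expect_equal(gu$m2_ns2, 4 + 2^2 / 12, tolerance = 1e-8)  # mean^2 + width^2/12
  # non-normalized density is rejected
  bad <- function(l) list(pdf = function(t) dunif(t, 1, 3) * 1.5,
                          lower = 0, upper = 5)
  expect_error(line_from_lifetime_distribution(bad, 1, ctx0), "normalized")
})

test_that("three-state limiting lines share the equal-mixture point", {
  states <- list(fret_state("1", E = 0.85), fret_state("2", E = 0.5),
                 fret_state("3", E = 0.15))
  ll <- limiting_lines_three_state(states, ctx0, 301)
  taus <- (1 - c(0.85, 0.5, 0.15)) * 4
  # pairwise endpoints are the pure states
  p12 <- ll$pairwise[[1]]
  expect_equal(p12$tauF_ns[c(1, nrow(p12))], taus[1:2])
  # the three special lines intersect at x = 1/3 each: the sample at
  # param 1/3 of every special line is the same point
  pts <- sapply(ll$special, function(l) {
    i <- which.min(abs(l$param - 1 / 3))
    c(l$E[i], l$Gamma[i])
  })
  expect_lt(max(abs(pts - rowMeans(pts))), 1e-6)
  # numeric intersection of special lines 1 and 2 in the Gamma plane
  # recovers the 1/3 point
  l1 <- ll$special[[1]]; l2 <- ll$special[[2]]
  d <- sapply(seq_len(nrow(l1)), function(i)
    min((l1$E[i] - l2$E)^2 + (l1$Gamma[i] - l2$Gamma)^2))
  expect_equal(l1$param[which.min(d)], 1 / 3, tolerance = 1e-2)
  # mixtures stay inside the pure-state triangle in the Gamma plane
  E_v <- 1 - taus / 4
  G_v <- taus / 4 - taus^2 / 16
  A <- rbind(E_v, G_v, c(1, 1, 1))
  set.seed(12)
  for (i in 1:1000) {
    x <- runif(3); x <- x / sum(x)
    m1 <- sum(x * taus); m2 <- sum(x * taus^2)
    pt <- c(1 - m1 / 4, m1 / 4 - m2 / 16)
    bary <- solve(A, c(pt, 1))
    expect_true(all(bary >= -1e-9))
  }
})

test_that("species fractions are recovered from the moment-plane position", {
  states <- list(fret_state("1", E = 0.85), fret_state("2", E = 0.5),
                 fret_state("3", E = 0.15))
  taus <- (1 - c(0.85, 0.5, 0.15)) * 4
  vertex1 <- c(1 - taus[1] / 4, taus[1] / 4 - taus[1]^2 / 16)
  expect_equal(unname(fractions_from_position(vertex1, states, ctx0)),
               c(1, 0, 0), tolerance = 1e-9)
  centroid_m1 <- mean(taus); centroid_m2 <- mean(taus^2)
  centroid <- c(1 - centroid_m1 / 4, centroid_m1 / 4 - centroid_m2 / 16)
  expect_equal(unname(fractions_from_position(centroid, states, ctx0)),
               rep(1 / 3, 3), tolerance = 1e-9)
  set.seed(5)
  for (i in 1:50) {
    x <- runif(3); x <- x / sum(x)
    m1 <- sum(x * taus); m2 <- sum(x * taus^2)
    pt <- c(1 - m1 / 4, m1 / 4 - m2 / 16)
    expect_equal(unname(fractions_from_position(pt, states, ctx0)), x,
                 tolerance = 1e-9)
  }
  expect_error(fractions_from_position(c(0.99, 0.001), states, ctx0),
               "outside.*barycentric")
})

test_that("mean-variance dynamic line is the expected parabola", {
  s1 <- fret_state(E = 0.8); s2 <- fret_state(E = 0.2)
  mv <- mean_variance_dynamic_line(s1, s2, ctx0, 201)
  expect_equal(mv$var_ns2[c(1, nrow(mv))], c(0, 0))
  i <- which.min(abs(mv$tau_mean_ns - 2.0))
  expect_equal(mv$var_ns2[i], 1.44)
  expect_equal(max(mv$var_ns2), ((3.2 - 0.8) / 2)^2, tolerance = 1e-4)
  expect_equal(mv$varE, mv$var_ns2 / 16)
})
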