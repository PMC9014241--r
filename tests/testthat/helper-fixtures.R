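# Shared fixtures: the canonical dye pair (R0 = 50 A, tau_D0 = 4 ns) and the
# two-state system with efficiencies 0.25 / 0.80 used across simulator tests.

ctx0 <- fret_context(R0 = 50, tau_D0 = 4)

two_state_model <- function(k12 = 1, k21 = 1) {
  kinetic_model(
    list(fret_state("low", E = 0.25), fret_state("high", E = 0.80)),
    matrix(c(0, k12, k21, 0), 2, 2))
}

# Maximum perpendicular distance of (x, y) points from the chord through
# their first and last point; the straightness measure for moment-plane lines.
chord_residual <- function(x, y) {
  p1 <- c(x[1], y[1]); p2 <- c(x[length(x)], y[length(y)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(max(sqrt((x - p1[1])^2 + (y - p1[2])^2)))
  max(abs((x - p1[1]) * v[2] - (y - p1[2]) * v[1])) / nv
}
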