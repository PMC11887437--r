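# internal geometry helpers

# Quasi-uniform points on the unit sphere (Fibonacci / golden-spiral lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)          # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- phi * (seq_len(n) - 1)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

# Minimum-image displacement components for an orthorhombic box.
min_image <- function(d, box_len) {
  d - box_len * round(d / box_len)
}

# Unweighted centre of mass of a position matrix.
centre_of_mass <- function(pos) colMeans(pos)

# Fold an angle in degrees to [0, 90] (axis, not vector, orientation).
fold_angle_90 <- function(deg) {
  a <- deg %% 180
  ifelse(a > 90, 180 - a, a)
}
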