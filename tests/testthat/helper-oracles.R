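# Independent oracles used across the suite; deliberately written with
# different formulations than the package code paths they check.

# Torsion via projections onto the plane normal to the central bond
# (Gram-Schmidt form, not the cross-product/atan2 form in dihedral()).
oracle_torsion_deg <- function(p) {
  b <- p[3, ] - p[2, ]
  b <- b / sqrt(sum(b^2))
  u <- (p[1, ] - p[2, ]) - sum((p[1, ] - p[2, ]) * b) * b
  v <- (p[4, ] - p[3, ]) - sum((p[4, ] - p[3, ]) * b) * b
  # IUPAC sign: positive when d is rotated clockwise from a, viewing
  # along b -> c, i.e. when (u x v) is antiparallel to the central bond
  s <- sum(c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1]) * b)
  atan2(-s, sum(u * v)) * 180 / pi
}

# Two-pass product-moment correlation, no shortcuts
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Uniform random rotation matrix (QR of Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Eyring relations evaluated directly from the constants, independent of
# the package's conversion helpers
oracle_dg_kcal <- function(t_half_s, T_K) {
  kB <- 1.380649e-23; h <- 6.62607015e-34; R <- 1.987204e-3
  1.987204e-3 * T_K * log(kB * T_K / h / (log(2) / t_half_s))
}
oracle_thalf_s <- function(dg, T_K) {
  kB <- 1.380649e-23; h <- 6.62607015e-34
  log(2) * h / (kB * T_K) * exp(dg / (1.987204e-3 * T_K))
}
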