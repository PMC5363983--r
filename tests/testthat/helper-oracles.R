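# Independent oracles used across tests.

# Closed-form two-sided 2x2 Fisher p: hypergeometric enumeration over the
# single free cell.
oracleFisher2x2 <- function(tab, tol = 1e-7) {
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); A <- sum(tab[, 1])
  k <- max(0, A - n2):min(n1, A)
  pk <- dhyper(k, n1, n2, A)
  pobs <- dhyper(tab[1, 1], n1, n2, A)
  sum(pk[pk <= pobs * (1 + tol)])
}

# Solve the three-parameter exponential decay D(t) = a + b*exp(-c*t)
# exactly through three (t, D) points.
oracleExpDecayFit <- function(t, D) {
  f <- function(c) (D[1] - D[2]) / (D[2] - D[3]) -
    (exp(-c * t[1]) - exp(-c * t[2])) / (exp(-c * t[2]) - exp(-c * t[3]))
  c <- uniroot(f, c(0.005, 2), tol = 1e-13)$root
  b <- (D[1] - D[2]) / (exp(-c * t[1]) - exp(-c * t[2]))
  a <- D[1] - b * exp(-c * t[1])
  c(a = a, b = b, c = c)
}

sampleSkewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}

# big vessel holding the reference bottom concentration at the standard
# ration, with negligible depletion by any realistic cohort
bigReferenceVessel <- function() {
  vessel(volume_mL = 8e5, bottomArea_cm2 = 9.6e5)
}
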