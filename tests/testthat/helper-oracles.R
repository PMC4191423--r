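# Independent oracles kept deliberately separate from the package's own
# numerics: plain bisection, no shared code paths.

# McGhee-von Hippel coverage by straight bisection on
# theta = (C/Kd) n (1-theta)^n / (1 - theta + theta/n)^(n-1)
oracleMvH <- function(C, Kd, n, tol = 1e-10) {
  if (C == 0) return(0)
  g <- function(th) th - (C / Kd) * n * (1 - th)^n /
    (1 - th + th / n)^(n - 1)
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Odijk high-force expansion of the inextensible WLC (cross-check only)
oracleOdijk <- function(force, Lp, L0, kT = 0.0138065 * 294.15) {
  L0 * (1 - 0.5 * sqrt(kT / (force * Lp)))
}

# default experimental grids
paperForces <- function() seq(10, 60, by = 10)
paperConcs <- function() c(2, 5, 10, 25, 50, 100, 150)
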