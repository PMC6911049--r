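# Independent oracles used by the tests. These deliberately avoid the
# package's solver internals: plain arithmetic, dense grids, brute force.

R_GAS <- 8.314462618e-3  # kJ/(mol K)

# dense log-grid scan for the five-species mass balance: scans ln[N],
# computes total monomer equivalents by direct arithmetic, locates the
# crossing of C_tot by linear interpolation of log(total), and returns
# per-monomer fractions at the interpolated root.
oracle_species <- function(K_S, K_U, K_H, K_H2, K_P, C_tot, P_tot = 0,
                           n_grid = 400001L) {
  lnx <- seq(log(C_tot) - log(1e14), log(C_tot), length.out = n_grid)
  x <- exp(lnx)
  S <- K_S * x
  U <- K_U * x
  H <- if (K_H > 0) exp(log(K_H) + 6 * log(pmax(S, 1e-320))) * (S > 0) else 0 * x
  H2 <- if (K_H2 > 0 && K_H > 0)
    exp(log(K_H2) + 2 * log(K_H) + 12 * log(pmax(S, 1e-320))) * (S > 0)
  else 0 * x
  NP <- K_P * x * P_tot / (1 + K_P * x)
  total <- x + S + U + NP + 6 * H + 12 * H2
  i <- which(total >= C_tot)[1]
  stopifnot(!is.na(i), i > 1L)
  # interpolate the crossing on log(total)
  w <- (log(C_tot) - log(total[i - 1])) /
    (log(total[i]) - log(total[i - 1]))
  lnx0 <- lnx[i - 1] + w * (lnx[i] - lnx[i - 1])
  x0 <- exp(lnx0)
  S0 <- K_S * x0; U0 <- K_U * x0
  H0 <- if (K_H > 0 && S0 > 0) exp(log(K_H) + 6 * log(S0)) else 0
  H20 <- if (K_H2 > 0 && K_H > 0 && S0 > 0)
    exp(log(K_H2) + 2 * log(K_H) + 12 * log(S0)) else 0
  NP0 <- K_P * x0 * P_tot / (1 + K_P * x0)
  c(frac_N = x0 / C_tot, frac_NP = NP0 / C_tot, frac_S = S0 / C_tot,
    frac_U = U0 / C_tot, frac_H = 6 * H0 / C_tot,
    frac_H2 = 12 * H20 / C_tot)
}

# random-but-reproducible draws of linkage constants and conditions on
# scales where all species can plausibly populate
draw_linkage_cases <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      K_S = 10^runif(n, -3, 1),
      K_U = 10^runif(n, -3, 1) * stats::rbinom(n, 1, 0.8),
      K_H = 10^runif(n, 12, 28) * stats::rbinom(n, 1, 0.8),
      K_H2 = 10^runif(n, 0, 5) * stats::rbinom(n, 1, 0.8),
      K_P = 10^runif(n, 2, 5) * stats::rbinom(n, 1, 0.5),
      C_tot = 10^runif(n, -6, -2),
      P_tot = 10^runif(n, -6, -2) * stats::rbinom(n, 1, 0.5))
  })
}

# two-state linkage parameter set (unfolding only), used for nested and
# closed-form limit checks
two_state_linkage <- function(Tm = 337, dHm = 300) {
  linkage_params(step_NU = thermal_step_params(Tm, dHm))
}
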