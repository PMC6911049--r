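test_that("equilibrium constants follow exp(-dG/RT) for every step type", {
  lp <- linkage_params(step_NU = thermal_step_params(337, 300),
                       assoc_H = assoc_step_params(-170, n = 6))
  ks <- equilibrium_constants(lp, 337)
  expect_equal(ks$K_U, 1)          # midpoint of the unfolding step
  expect_equal(ks$K_S, 0)          # disabled step
  # hand evaluation: ln K_H = 170/(R*298)
  ks298 <- equilibrium_constants(lp, 298)
  expect_equal(ks298$lnK_H, 68.6117, tolerance = 1e-4)
  expect_error(equilibrium_constants(lp, -1), "positive")
})

test_that("inert monomer and pure two-state splits solve exactly", {
  st <- solve_species_k(0, 0, 0, 0, 0, C_tot = 1e-4)
  expect_equal(st$frac_N, 1, tolerance = 1e-9)
  expect_equal(st$frac_S + st$frac_U + st$frac_H + st$frac_H2 + st$frac_NP,
               0, tolerance = 1e-12)
  expect_equal(monomer_fraction(st), 1, tolerance = 1e-9)
  st2 <- solve_species_k(1, 0, 0, 0, 0, C_tot = 1e-4)
  expect_equal(st2$frac_N, 0.5, tolerance = 1e-9)
  expect_equal(st2$frac_S, 0.5, tolerance = 1e-9)
})

test_that("solver matches the dense log-grid oracle on the assembly-heavy case", {
  st <- solve_species_k(K_S = 0.1, K_U = 0, K_H = 1e30, K_H2 = 1e4, K_P = 0,
                        C_tot = 1e-3)
  orc <- oracle_species(0.1, 0, 1e30, 1e4, 0, 1e-3)
  got <- c(st$frac_N, st$frac_NP, st$frac_S, st$frac_U, st$frac_H, st$frac_H2)
  expect_equal(got, unname(orc), tolerance = 1e-6)
  expect_equal(monomer_fraction(st),
               unname(orc["frac_N"] + orc["frac_NP"] + orc["frac_S"] +
                        orc["frac_U"]),
               tolerance = 1e-6)
})

test_that("solver matches the grid-scan oracle across 50 randomised cases", {
  cases <- draw_linkage_cases(50, seed = 2024)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    st <- solve_species_k(cs$K_S, cs$K_U, cs$K_H, cs$K_H2, cs$K_P,
                          cs$C_tot, cs$P_tot)
    orc <- oracle_species(cs$K_S, cs$K_U, cs$K_H, cs$K_H2, cs$K_P,
                          cs$C_tot, cs$P_tot)
    got <- c(st$frac_N, st$frac_NP, st$frac_S, st$frac_U, st$frac_H,
             st$frac_H2)
    expect_equal(got, unname(orc), tolerance = 1e-6)
  }
})

test_that("mass conservation and detailed balance hold on 1000 random draws", {
  cases <- draw_linkage_cases(1000, seed = 77)
  st <- solve_species_k(cases$K_S, cases$K_U, cases$K_H, cases$K_H2,
                        cases$K_P, cases$C_tot, cases$P_tot)
  frac_sum <- st$frac_N + st$frac_NP + st$frac_S + st$frac_U +
    st$frac_H + st$frac_H2
  expect_lt(max(abs(frac_sum - 1)), 1e-9)
  # peptide balance
  expect_lt(max(abs((st$conc_P_free + st$conc_NP) - cases$P_tot) /
                  pmax(cases$P_tot, 1e-300)), 1e-9)
  # detailed balance where the species actually populate
  rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)
  ok_S <- cases$K_S > 0
  expect_lt(max(rel_err(st$conc_S[ok_S] / st$conc_N[ok_S],
                        cases$K_S[ok_S])), 1e-8)
  ok_H <- cases$K_H > 0 & st$conc_H > 1e-250 & st$conc_S > 1e-40
  expect_lt(max(rel_err(st$conc_H[ok_H] / st$conc_S[ok_H]^6,
                        cases$K_H[ok_H])), 1e-8)
  ok_H2 <- cases$K_H2 > 0 & st$conc_H2 > 1e-250 & st$conc_H > 1e-125
  expect_lt(max(rel_err(st$conc_H2[ok_H2] / st$conc_H[ok_H2]^2,
                        cases$K_H2[ok_H2])), 1e-8)
  ok_P <- cases$K_P > 0 & st$conc_NP > 1e-250
  expect_lt(max(rel_err(st$conc_NP[ok_P] /
                          (st$conc_N[ok_P] * st$conc_P_free[ok_P]),
                        cases$K_P[ok_P])), 1e-8)
})

test_that("the dilute limit reduces to the three-state monomer closed form", {
  lp <- ci2_fixture("ci2_eng_linkage")
  for (Tt in c(300, 320, 340)) {
    ks <- equilibrium_constants(lp, Tt)
    st <- solve_species(lp, conditions(C_tot = 1e-12, T = Tt))
    denom <- 1 + ks$K_S + ks$K_U
    expect_equal(st$frac_N, 1 / denom, tolerance = 1e-8)
    expect_equal(st$frac_S, ks$K_S / denom, tolerance = 1e-8)
    expect_equal(st$frac_U, ks$K_U / denom, tolerance = 1e-8)
    expect_lt(assembled_fraction(st), 1e-8)
  }
})

test_that("apparent native midpoint recovers the two-state Tm and drops with concentration", {
  # assembly off: closed-form two-state midpoint
  lp0 <- two_state_linkage(Tm = 337, dHm = 300)
  expect_equal(apparent_native_midpoint(lp0, C_tot = 5e-5,
                                        T_grid = seq(320, 350, 0.05)),
               337, tolerance = 0.05)
  # default fixture: strong destabilisation with concentration
  lp <- ci2_fixture("ci2_eng_linkage")
  grid <- seq(280, 375, 0.25)
  m6 <- apparent_native_midpoint(lp, 6e-6, T_grid = grid)
  m600 <- apparent_native_midpoint(lp, 600e-6, T_grid = grid)
  expect_lt(m600, m6)
  # grid far below any transition: explicit no-transition signal
  expect_warning(
    out <- apparent_native_midpoint(lp, 6e-6, T_grid = seq(280, 290, 0.5)),
    "no transition")
  expect_true(is.na(out))
})

test_that("apparent midpoint decreases strictly across a concentration ladder", {
  lp <- ci2_fixture("ci2_eng_linkage")
  grid <- seq(280, 375, 0.25)
  mids <- vapply(c(6e-6, 60e-6, 200e-6, 600e-6), function(cc)
    apparent_native_midpoint(lp, cc, T_grid = grid), numeric(1))
  expect_true(all(diff(mids) < 0))
})

test_that("assembled fraction rises with concentration and rises then falls with temperature", {
  lp <- ci2_fixture("ci2_eng_linkage")
  # nondecreasing in C_tot at fixed T
  Cs <- 10^seq(-6, -2.5, length.out = 12)
  st <- solve_species(lp, conditions(C_tot = Cs, T = 320))
  expect_true(all(diff(assembled_fraction(st)) > -1e-12))
  # switch-in then unfold-out across temperature
  st2 <- solve_species(lp, conditions(C_tot = 600e-6, T = seq(285, 375, 1)))
  af <- assembled_fraction(st2)
  ipk <- which.max(af)
  expect_gt(max(af), 0.5)
  expect_true(ipk > 1 && ipk < length(af))
  expect_lt(af[1], 0.01)
  expect_lt(af[length(af)], 0.01)
  expect_true(all(diff(af[1:ipk]) > -1e-12))
  expect_true(all(diff(af[ipk:length(af)]) < 1e-12))
})

test_that("peptide rescue is monotone, consistent at zero, and weaker when assemblies are more stable", {
  l8 <- ci2_fixture("ci2_158_linkage")
  P <- seq(0, 1e-2, length.out = 101)
  cv <- peptide_rescue_curve(l8, C_tot = 80e-6, T = 298, P_grid = P)
  expect_true(all(diff(cv$y) > -1e-12))
  # zero-peptide entry equals the direct solve
  st0 <- solve_species(l8, conditions(C_tot = 80e-6, T = 298))
  expect_equal(cv$y[1], monomer_fraction(st0), tolerance = 1e-12)
  # saturating peptide returns everything monomeric
  expect_gt(cv$y[length(cv$y)], 0.95)
  # inert peptide: flat curve
  l8_nop <- linkage_params(step_NS = l8$step_NS, step_NU = l8$step_NU,
                           assoc_H = l8$assoc_H, assoc_H2 = l8$assoc_H2)
  cv0 <- peptide_rescue_curve(l8_nop, 80e-6, 298, P_grid = P)
  expect_equal(diff(range(cv0$y)), 0, tolerance = 1e-12)
  # warmer assemblies are more stable: half rescue needs more peptide
  h298 <- half_rescue_point(peptide_rescue_curve(l8, 80e-6, 298, P))
  h310 <- half_rescue_point(peptide_rescue_curve(l8, 80e-6, 310, P))
  expect_gt(h310, h298)
})

test_that("pathological constants are reported, not silently mis-solved", {
  # so much assembly that even the lower bracket overshoots
  expect_error(solve_species_k(1e5, 0, 1e300, 0, 0, C_tot = 1),
               "bracket")
  expect_error(solve_species_k(-1, 0, 0, 0, 0, C_tot = 1e-4), "nonnegative")
  expect_error(conditions(C_tot = 0), "positive")
})
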