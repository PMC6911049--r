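lp_eng <- ci2_fixture("ci2_eng_linkage")

test_that("melt curves are population-weighted baselines", {
  # all species sharing one baseline: the curve is that baseline exactly
  shared <- signal_basis(
    intercepts = c(N = 2, NP = 2, S = 2, U = 2, H = 2, H2 = 2),
    slopes = c(N = 0.01, NP = 0.01, S = 0.01, U = 0.01, H = 0.01, H2 = 0.01))
  Tg <- seq(290, 360, 5)
  cv <- melt_curve(lp_eng, shared, C_tot = 1e-4, T_grid = Tg)
  expect_equal(cv$y, 2 + 0.01 * Tg, tolerance = 1e-9)
  # assembly off, two-state N/U basis with zero slopes: sigmoid with
  # midpoint at the unfolding Tm
  lp0 <- two_state_linkage(Tm = 337, dHm = 300)
  cv2 <- melt_curve(lp0, signal_basis(), C_tot = 5e-5,
                    T_grid = seq(300, 370, 0.5))
  expect_true(all(diff(cv2$y) < 0))
  expect_equal(approx(cv2$y, cv2$x, xout = 0.5)$y, 337, tolerance = 0.05)
  # concentration pushes the native-loss transition down in temperature
  Tg <- seq(280, 375, 0.5)
  lo <- melt_curve(lp_eng, signal_basis(), C_tot = 6e-6, T_grid = Tg)
  hi <- melt_curve(lp_eng, signal_basis(), C_tot = 600e-6, T_grid = Tg)
  mid_lo <- approx(lo$y, lo$x, xout = 0.5)$y
  mid_hi <- approx(hi$y, hi$x, xout = 0.5)$y
  expect_lt(mid_hi, mid_lo)
})

test_that("excess enthalpy recombines species fractions and step enthalpies", {
  # reference state: essentially all native at low temperature, so the
  # excess enthalpy is a negligible fraction of the 100 kJ/mol switch step
  h <- excess_enthalpy(lp_eng, conditions(C_tot = 6e-6, T = 280))
  expect_lt(abs(h), 0.01)
  # two-state limit at Tm: half converted, h = dHm/2
  lp0 <- two_state_linkage(Tm = 337, dHm = 300)
  expect_equal(excess_enthalpy(lp0, conditions(C_tot = 5e-5, T = 337)),
               150, tolerance = 1e-6)
  # independent recomposition from solved fractions mid-transition
  cond <- conditions(C_tot = 600e-6, T = 325)
  st <- solve_species(lp_eng, cond)
  dH_NS <- lp_eng$step_NS$dHm + lp_eng$step_NS$dCp * (325 - lp_eng$step_NS$Tm)
  dH_NU <- lp_eng$step_NU$dHm + lp_eng$step_NU$dCp * (325 - lp_eng$step_NU$Tm)
  dH_H <- lp_eng$assoc_H$dH_ref + lp_eng$assoc_H$dCp * (325 - lp_eng$assoc_H$T_ref)
  dH_H2 <- lp_eng$assoc_H2$dH_ref + lp_eng$assoc_H2$dCp * (325 - lp_eng$assoc_H2$T_ref)
  manual <- st$frac_S * dH_NS + st$frac_U * dH_NU +
    st$frac_H * (dH_NS + dH_H / 6) +
    st$frac_H2 * (dH_NS + dH_H / 6 + dH_H2 / 12)
  expect_equal(excess_enthalpy(lp_eng, cond), manual, tolerance = 1e-10)
})

test_that("two-state DSC peak matches the closed-form van't Hoff maximum", {
  lp0 <- two_state_linkage(Tm = 337, dHm = 300)
  d <- dsc_thermogram(lp0, C_tot = 5e-5, T_grid = seq(300, 370, 0.1))
  expect_length(d$peaks, 1)
  expect_equal(d$peaks, 337, tolerance = 0.1 + 0.02)
  peak_height <- max(d$trace$Cp_excess_kJ_per_mol_K)
  # closed form dHm^2/(4 R Tm^2) = 23.828
  expect_equal(peak_height, 300^2 / (4 * R_GAS * 337^2), tolerance = 0.005)
  expect_equal(peak_height, 23.828, tolerance = 0.005)
})

test_that("thermograms integrate back to the enthalpy change across the scan", {
  grid <- seq(280, 375, 0.25)
  d <- dsc_thermogram(lp_eng, C_tot = 600e-6, T_grid = grid)
  cp <- d$trace$Cp_excess_kJ_per_mol_K
  integral <- sum((cp[-1] + cp[-length(cp)]) / 2 * diff(grid))
  dh <- excess_enthalpy(lp_eng, conditions(600e-6, max(grid))) -
    excess_enthalpy(lp_eng, conditions(600e-6, min(grid)))
  expect_equal(integral, dh, tolerance = 0.005)
})

test_that("DSC develops a second peak with concentration and the peaks move apart", {
  grid <- seq(280, 375, 0.25)
  p6 <- dsc_thermogram(lp_eng, 6e-6, T_grid = grid)$peaks
  expect_length(p6, 1)
  p600 <- dsc_thermogram(lp_eng, 600e-6, T_grid = grid)$peaks
  expect_length(p600, 2)
  seps <- vapply(c(60e-6, 200e-6, 600e-6), function(cc) {
    pk <- dsc_thermogram(lp_eng, cc, T_grid = grid)$peaks
    expect_length(pk, 2)
    diff(pk)
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})

test_that("flat traces yield an empty peak list and bad steps are rejected", {
  # no transitions anywhere near the scanned window
  lp_far <- linkage_params(step_NU = thermal_step_params(500, 300))
  d <- dsc_thermogram(lp_far, 1e-4, T_grid = seq(280, 320, 0.5))
  expect_length(d$peaks, 0)
  expect_error(dsc_thermogram(lp_eng, 1e-4, T_grid = seq(280, 320, 0.5),
                              dT = 0.3), "spacing")
  expect_error(dsc_thermogram(lp_eng, 1e-4, dT = -1), "positive")
})

test_that("species distributions pool monomers and scale masses 1x/6x/12x", {
  m1 <- average_mass("MDAKTEWPELVGKSLEEAKKALLQDKPEATIIVIPVGTIVTMEYRVDRVRIVVDKLDNIAEVPTVG")
  # inert monomer
  lp0 <- linkage_params(step_NU = thermal_step_params(400, 300))
  sd0 <- species_distribution(lp0, conditions(1e-4, 298), m1)
  expect_equal(sd0$fraction[sd0$species == "M"], 1, tolerance = 1e-9)
  expect_equal(sd0$fraction[sd0$species == "H"], 0, tolerance = 1e-12)
  # masses land on the light-scattering values: ~7.3, 44, 88 kDa
  expect_equal(sd0$mass_da[sd0$species == "M"] / 1000, 7.33, tolerance = 0.01)
  expect_equal(round(sd0$mass_da[sd0$species == "H"] / 1000), 44)
  expect_equal(round(sd0$mass_da[sd0$species == "H2"] / 1000), 88)
  # fractions equal the pooled solver fractions mid-assembly
  cond <- conditions(600e-6, 325)
  tab <- species_distribution(lp_eng, cond, m1)
  st <- solve_species(lp_eng, cond)
  expect_equal(tab$fraction[tab$species == "M"], monomer_fraction(st))
  expect_equal(tab$fraction[tab$species == "H"], st$frac_H)
  expect_equal(tab$fraction[tab$species == "H2"], st$frac_H2)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
})

test_that("observable objects render with ggplot2", {
  d <- dsc_thermogram(two_state_linkage(), 5e-5, T_grid = seq(320, 350, 0.5))
  expect_s3_class(autoplot(d), "ggplot")
  st <- solve_species(lp_eng, conditions(600e-6, seq(300, 360, 5)))
  expect_s3_class(autoplot(st), "ggplot")
  cv <- melt_curve(lp_eng, signal_basis(), 600e-6, T_grid = seq(300, 360, 5))
  expect_s3_class(autoplot(cv), "ggplot")
})
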