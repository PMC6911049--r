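wt <- ci2_fixture("ci2_wt")
eng <- ci2_fixture("ci2_eng")

test_that("every fitter recovers its generator exactly on noise-free data", {
  f1 <- fit_lem(gen_chem_denaturation(wt$chem, noise = noise_spec(0)))
  expect_equal(unname(coef(f1)["dG0"]), 30.9, tolerance = 1e-6)
  expect_equal(unname(coef(f1)["Cm"]), 4.07, tolerance = 1e-6)
  f2 <- fit_lem(gen_chem_denaturation(eng$chem, seq(0, 5, length.out = 25),
                                      noise = noise_spec(0)))
  expect_equal(unname(coef(f2)["dG0"]), 10.9, tolerance = 1e-6)
  expect_equal(unname(coef(f2)["Cm"]), 1.28, tolerance = 1e-6)
  f3 <- fit_chevron(gen_chevron(wt$chevron,
                                noise = noise_spec(0, relative = FALSE)))
  expect_equal(unname(coef(f3)["kf0"]), 44, tolerance = 1e-6)
  expect_equal(unname(coef(f3)["ku0"]), 1.9e-4, tolerance = 1e-6)
  f4 <- fit_chevron(gen_chevron(eng$chevron,
                                noise = noise_spec(0, relative = FALSE)))
  expect_equal(unname(coef(f4)["kf0"]), 25, tolerance = 1e-6)
  expect_equal(unname(coef(f4)["ku0"]), 0.58, tolerance = 1e-6)
  lp0 <- two_state_linkage(Tm = 337, dHm = 300)
  cv <- melt_curve(lp0, signal_basis(), C_tot = 5e-5,
                   T_grid = seq(300, 370, 1))
  f5 <- fit_thermal_two_state(cv)
  expect_equal(unname(coef(f5)["Tm"]), 337, tolerance = 1e-6)
  expect_equal(unname(coef(f5)["dHm"]), 300, tolerance = 1e-4)
  expect_true(all(c(f1$converged, f3$converged, f5$converged)))
})

test_that("fit objects expose broom-style tidy and glance views", {
  f <- fit_lem(gen_chem_denaturation(wt$chem, noise = noise_spec(0.02, 3)))
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("Cm" %in% td$term)
  gl <- glance(f)
  expect_equal(gl$nobs, 25)
  expect_true(is.finite(gl$sigma))
  expect_output(print(f), "fold_fit")
})

test_that("chevron fits demand both arms", {
  # folding arm only: minimum at the right edge
  cv <- gen_chevron(wt$chevron, D_grid = seq(0, 8, length.out = 15),
                    noise = noise_spec(0, relative = FALSE))
  expect_error(fit_chevron(cv), "ill-conditioned")
})

test_that("narrow thermal grids warn about Tm/dHm confounding", {
  lp0 <- two_state_linkage(Tm = 337, dHm = 300)
  cv <- melt_curve(lp0, signal_basis(), C_tot = 5e-5,
                   T_grid = seq(334, 340, 0.25))
  expect_warning(fit_thermal_two_state(cv), "confounded")
})

test_that("recovery error shrinks monotonically with noise", {
  rmse_at <- function(sd) {
    rec <- recovery_study(
      generate = function(s)
        gen_chem_denaturation(wt$chem, noise = noise_spec(sd, s)),
      fit = fit_lem, true = c(Cm = 4.07), R = 30, seed = 21)
    rec$rmse[rec$term == "Cm"]
  }
  r <- vapply(c(0.02, 0.01, 0.005), rmse_at, numeric(1))
  expect_true(all(diff(r) < 0))
  # a noise-free single replicate is exact and the report is well-formed
  rec0 <- recovery_study(
    generate = function(s) gen_chem_denaturation(wt$chem,
                                                 noise = noise_spec(0, s)),
    fit = fit_lem, true = c(dG0 = 30.9, Cm = 4.07), R = 1, seed = 1)
  expect_equal(rec0$bias, c(0, 0), tolerance = 1e-6)
  expect_true(all(rec0$rmse >= abs(rec0$bias)))
  gl <- glance(rec0)
  expect_named(gl, c("R", "n_fail", "failure_rate", "seed"))
  expect_equal(gl$failure_rate, 0)
})

test_that("fitter failures are counted, not dropped", {
  flaky <- local({
    i <- 0
    function(curve) {
      i <<- i + 1
      if (i %% 3 == 0) stop("synthetic failure")
      fit_lem(curve)
    }
  })
  rec <- recovery_study(
    generate = function(s) gen_chem_denaturation(wt$chem,
                                                 noise = noise_spec(0.02, s)),
    fit = flaky, true = c(Cm = 4.07), R = 9, seed = 4)
  expect_equal(attr(rec, "n_fail"), 3)
  expect_equal(glance(rec)$failure_rate, 1 / 3)
})

test_that("global linkage fits recover conformational and association energies", {
  lp <- ci2_fixture("ci2_eng_linkage")
  ser <- gen_thermal_melts(lp, C_tot = c(60e-6, 200e-6, 600e-6),
                           T_grid = seq(285, 370, 2.5),
                           noise = noise_spec(0.01, seed = 11))
  lp0 <- lp
  lp0$step_NS$Tm <- 352
  lp0$assoc_H$dG_ref <- -150
  fit <- fit_linkage_global(ser, lp0, free = c("step_NS.Tm", "assoc_H.dG_ref"),
                            restarts = 0)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["step_NS.Tm"]), 359, tolerance = 0.05)
  expect_equal(unname(coef(fit)["assoc_H.dG_ref"]), -170, tolerance = 0.05)
  expect_s3_class(fit$extra$params, "linkage_params")
})

test_that("peptide-binding affinity is recovered from a titration", {
  l8 <- ci2_fixture("ci2_158_linkage")
  tit <- gen_peptide_titration(l8, 80e-6, 298,
                               seq(0, 2e-3, length.out = 25),
                               noise = noise_spec(0.01, seed = 5))
  l80 <- l8
  l80$bind_P$dG_ref <- -20
  fit <- fit_linkage_global(tit, l80, free = "bind_P.dG_ref", restarts = 0)
  expect_equal(unname(coef(fit)["bind_P.dG_ref"]), -23, tolerance = 0.1)
})

test_that("a single-concentration linkage fit reduces to the thermal two-state fit", {
  lp0 <- two_state_linkage(Tm = 337, dHm = 300)
  Tg <- seq(300, 370, 1)
  cv <- melt_curve(lp0, signal_basis(), C_tot = 5e-5, T_grid = Tg)
  direct <- fit_thermal_two_state(cv)
  start <- lp0
  start$step_NU$Tm <- 330
  start$step_NU$dHm <- 250
  nested <- fit_linkage_global(cv, start,
                               free = c("step_NU.Tm", "step_NU.dHm"),
                               restarts = 0)
  expect_equal(unname(coef(nested)["step_NU.Tm"]),
               unname(coef(direct)["Tm"]), tolerance = 1e-3)
  expect_equal(unname(coef(nested)["step_NU.dHm"]),
               unname(coef(direct)["dHm"]), tolerance = 1e-2)
})

test_that("unidentifiable masks are refused", {
  lp <- ci2_fixture("ci2_eng_linkage")
  one_conc <- gen_thermal_melts(lp, C_tot = 600e-6,
                                T_grid = seq(290, 370, 5),
                                noise = noise_spec(0))
  expect_error(fit_linkage_global(one_conc, lp, free = "assoc_H.dG_ref",
                                  restarts = 0),
               "unidentifiable")
  expect_error(fit_linkage_global(one_conc, lp, free = "bind_P.dG_ref",
                                  restarts = 0),
               "disabled|titration")
})
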