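# Fitting layer: weighted nonlinear least squares per model plus global
# linkage fits across condition series. All fitters are multi-start
# (data-driven start first, Latin-hypercube restarts within bounds on
# failure) and return a `fold_fit` with broom-style tidy()/glance()
# methods. Standard errors come from the local quadratic approximation.

new_fold_fit <- function(model, estimates, se = NULL, rss = NA_real_,
                         converged = TRUE, n_restarts = 0L, nobs = NA_integer_,
                         data = NULL, extra = list()) {
  if (is.null(se)) se <- setNames(rep(NA_real_, length(estimates)),
                                  names(estimates))
  structure(list(model = model, estimates = estimates, se = se, rss = rss,
                 converged = converged, n_restarts = n_restarts, nobs = nobs,
                 data = data, extra = extra,
                 seed = attr(data, "seed"), config = attr(data, "config")),
            class = "fold_fit")
}

.fold_fit_from_nls <- function(fit, model, data, derived = NULL,
                               n_restarts = 0L) {
  est <- coef(fit)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  se <- if (!is.null(sm)) sm$coefficients[, "Std. Error"] else
    setNames(rep(NA_real_, length(est)), names(est))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(derived)) {
    dd <- derived(est, vc)
    est <- c(est, dd$estimates)
    se <- c(se, dd$se)
  }
  new_fold_fit(model, est, se,
               rss = sum(stats::resid(fit)^2),
               converged = fit$convInfo$isConv %||% TRUE,
               n_restarts = n_restarts,
               nobs = length(stats::resid(fit)), data = data)
}

#' @export
coef.fold_fit <- function(object, ...) object$estimates

#' @export
print.fold_fit <- function(x, ...) {
  cat(sprintf("<fold_fit: %s, %s, rss = %.4g, %d restart(s)>\n", x$model,
              if (x$converged) "converged" else "NOT CONVERGED (estimates non-authoritative)",
              x$rss, x$n_restarts))
  print(round(rbind(estimate = x$estimates, std.error = x$se), 6))
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x A `fold_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.fold_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(x$se[names(x$estimates)]))
}

#' One-row fit summary
#'
#' @param x A `fold_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `rss`, `sigma`, `nobs`, `converged`,
#'   `n_restarts`.
#' @export
glance.fold_fit <- function(x, ...) {
  p <- length(x$estimates)
  tibble(model = x$model, rss = x$rss,
         sigma = sqrt(x$rss / max(x$nobs - p, 1)),
         nobs = x$nobs, converged = x$converged,
         n_restarts = x$n_restarts)
}

# multi-start nlsLM: data-driven start, then Latin-hypercube draws in
# [lower, upper]; returns best converged fit or aborts
.multistart_nls <- function(formula, data, start, lower, upper,
                            restarts = 20L, weights = NULL) {
  try_one <- function(st) {
    args <- list(formula, data = data, start = as.list(st),
                 lower = lower[names(st)], upper = upper[names(st)],
                 control = minpack.lm::nls.lm.control(maxiter = 500))
    if (!is.null(weights)) args$weights <- weights
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  }
  best <- try_one(unlist(start))
  n_used <- 0L
  if (restarts > 0L) {
    pn <- names(start)
    draws <- lhs::randomLHS(restarts, length(pn))
    for (i in seq_len(restarts)) {
      if (!is.null(best)) break
      n_used <- n_used + 1L
      st <- setNames(lower[pn] + draws[i, ] * (upper[pn] - lower[pn]), pn)
      best <- try_one(st)
    }
  }
  if (is.null(best))
    abort("Nonlinear fit failed to converge after multi-start cap.")
  list(fit = best, n_restarts = n_used)
}

#' Fit the linear extrapolation model to a chemical denaturation curve
#'
#' Weighted nonlinear least squares of the two-state signal model
#' \eqn{y(D) = (a_N + b_N D)(1 - f_U) + (a_U + b_U D) f_U} with
#' \eqn{f_U = 1/(1 + \exp((\Delta G_0 - m_{eq} D)/(RT)))}. Recovers the
#' generating parameters to machine-level accuracy on noise-free data
#' and reports the midpoint `Cm = dG0/m_eq` (standard error by the
#' delta method).
#'
#' @param curve A [curve_table()] with `x` = denaturant (M), `y` =
#'   signal; must span the transition.
#' @param T Temperature, K.
#' @param restarts Latin-hypercube restart cap used if the data-driven
#'   start fails. Default 20.
#' @return A `fold_fit` with estimates `dG0`, `m_eq`, `aN`, `bN`, `aU`,
#'   `bU` and derived `Cm`.
#' @examples
#' wt <- ci2_fixture("ci2_wt")$chem
#' cv <- gen_chem_denaturation(wt, noise = noise_spec(0))
#' coef(fit_lem(cv))[c("dG0", "Cm")]
#' @export
fit_lem <- function(curve, T = 298, restarts = 20L) {
  D <- curve$x; y <- curve$y
  RT <- .R * T
  k <- max(3L, round(length(D) / 6))
  aN0 <- mean(head(y, k)); aU0 <- mean(tail(y, k))
  mid <- (aN0 + aU0) / 2
  Cm0 <- D[which.min(abs(y - mid))]
  Cm0 <- max(Cm0, 0.2)
  start <- list(dG0 = max(4 * Cm0, 5), m_eq = max(4, 5 / Cm0),
                aN = aN0, bN = 0, aU = aU0, bU = 0)
  start$m_eq <- start$dG0 / Cm0
  rng <- diff(range(y))
  lower <- c(dG0 = 0.5, m_eq = 0.1, aN = min(y) - 5 * rng, bN = -5 * rng,
             aU = min(y) - 5 * rng, bU = -5 * rng)
  upper <- c(dG0 = 300, m_eq = 150, aN = max(y) + 5 * rng, bN = 5 * rng,
             aU = max(y) + 5 * rng, bU = 5 * rng)
  ms <- .multistart_nls(
    y ~ (aN + bN * D) * (1 - 1 / (1 + exp((dG0 - m_eq * D) / RT))) +
      (aU + bU * D) / (1 + exp((dG0 - m_eq * D) / RT)),
    data = data.frame(D = D, y = y, RT = RT),
    start = start, lower = lower, upper = upper, restarts = restarts)
  derived <- function(est, vc) {
    Cm <- est[["dG0"]] / est[["m_eq"]]
    se <- NA_real_
    if (!is.null(vc)) {
      g <- c(1 / est[["m_eq"]], -est[["dG0"]] / est[["m_eq"]]^2)
      v <- vc[c("dG0", "m_eq"), c("dG0", "m_eq")]
      se <- sqrt(drop(t(g) %*% v %*% g))
    }
    list(estimates = c(Cm = Cm), se = c(Cm = se))
  }
  .fold_fit_from_nls(ms$fit, "lem_two_state", curve, derived = derived,
                     n_restarts = ms$n_restarts)
}

#' Fit a chevron plot (log relaxation rate vs denaturant)
#'
#' Least squares in log-rate space of
#' \eqn{\ln \lambda(D) = \ln[k_f^0 e^{m_f D/RT} + k_u^0 e^{m_u D/RT}]},
#' matching the log-normal error structure of measured rates. The curve
#' must cover both chevron arms: data whose minimum lies at the edge of
#' the grid are flagged as ill-conditioned.
#'
#' @param curve A [curve_table()] (kind `"chevron"`) with `y` = ln(rate).
#' @param T Temperature, K.
#' @param restarts Restart cap. Default 20.
#' @return A `fold_fit` with estimates `kf0`, `ku0`, `mf`, `mu` (rates
#'   back-transformed from the log scale; standard errors by the delta
#'   method).
#' @examples
#' wt <- ci2_fixture("ci2_wt")$chevron
#' cv <- gen_chevron(wt, noise = noise_spec(0, relative = FALSE))
#' coef(fit_chevron(cv))
#' @export
fit_chevron <- function(curve, T = 298, restarts = 20L) {
  D <- curve$x; y <- curve$y
  n <- length(D)
  imin <- which.min(y)
  if (imin <= 2L || imin >= n - 1L)
    abort(paste("Chevron minimum lies at the edge of the data: single-arm",
                "data are ill-conditioned for a four-parameter fit."))
  RT <- .R * T
  k <- max(3L, min(5L, imin - 1L))
  f_arm <- stats::lm(y ~ D, data = data.frame(D = D[1:k], y = y[1:k]))
  ku_pts <- seq(max(imin + 1L, n - 4L), n)
  u_arm <- stats::lm(y ~ D, data = data.frame(D = D[ku_pts], y = y[ku_pts]))
  start <- list(lnkf0 = unname(coef(f_arm)[1]),
                mf = min(unname(coef(f_arm)[2]) * RT, 0),
                lnku0 = unname(coef(u_arm)[1]),
                mu = max(unname(coef(u_arm)[2]) * RT, 0))
  lower <- c(lnkf0 = -50, mf = -50, lnku0 = -50, mu = 0)
  upper <- c(lnkf0 = 50, mf = 0, lnku0 = 50, mu = 50)
  ms <- .multistart_nls(
    y ~ log(exp(lnkf0 + mf * D / RT) + exp(lnku0 + mu * D / RT)),
    data = data.frame(D = D, y = y, RT = RT),
    start = start, lower = lower, upper = upper, restarts = restarts)
  fit <- ms$fit
  est <- coef(fit)
  sm <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(est)))
  out_est <- c(kf0 = exp(est[["lnkf0"]]), ku0 = exp(est[["lnku0"]]),
               mf = est[["mf"]], mu = est[["mu"]])
  out_se <- c(kf0 = exp(est[["lnkf0"]]) * sm[["lnkf0"]],
              ku0 = exp(est[["lnku0"]]) * sm[["lnku0"]],
              mf = sm[["mf"]], mu = sm[["mu"]])
  new_fold_fit("chevron", out_est, out_se,
               rss = sum(stats::resid(fit)^2),
               converged = fit$convInfo$isConv %||% TRUE,
               n_restarts = ms$n_restarts, nobs = n, data = curve)
}

#' Fit a thermal two-state melt
#'
#' Two-state Gibbs-Helmholtz signal model with linear baselines:
#' \eqn{y(T) = (a_N + b_N T)(1 - f_U) + (a_U + b_U T) f_U} with
#' \eqn{f_U} from [frac_unfolded_thermal()]. The heat-capacity change
#' is fixed (default 0, the usual choice for optical melts) unless
#' `fit_dCp = TRUE`. A narrow grid that never approaches the baselines
#' leaves `Tm` and `dHm` strongly confounded; a warning is issued.
#'
#' @param curve A [curve_table()] with `x` = temperature (K), `y` =
#'   signal.
#' @param fit_dCp Free the heat-capacity change? Default `FALSE`.
#' @param restarts Restart cap. Default 20.
#' @return A `fold_fit` with estimates `Tm`, `dHm` (and `dCp` if freed)
#'   plus baselines.
#' @export
fit_thermal_two_state <- function(curve, fit_dCp = FALSE, restarts = 20L) {
  Tg <- curve$x; y <- curve$y
  k <- max(3L, round(length(Tg) / 6))
  aN0 <- mean(head(y, k)); aU0 <- mean(tail(y, k))
  Tm0 <- Tg[which.min(abs(y - (aN0 + aU0) / 2))]
  # if the signal is still changing steeply at either end of the grid the
  # baselines are unconstrained and Tm/dHm trade off against them
  dy <- abs(diff(y))
  if (max(dy) > 0 &&
      max(mean(head(dy, 2)), mean(tail(dy, 2))) > 0.25 * max(dy))
    warn("Melt grid barely leaves the transition: Tm and dHm are confounded.")
  rng <- diff(range(y))
  start <- list(Tm = Tm0, dHm = 300, aN = aN0, bN = 0, aU = aU0, bU = 0)
  lower <- c(Tm = min(Tg) - 50, dHm = 10, aN = min(y) - 5 * rng, bN = -rng,
             aU = min(y) - 5 * rng, bU = -rng, dCp = -50)
  upper <- c(Tm = max(Tg) + 50, dHm = 3000, aN = max(y) + 5 * rng, bN = rng,
             aU = max(y) + 5 * rng, bU = rng, dCp = 50)
  Rgas <- .R
  if (fit_dCp) {
    start$dCp <- 0
    form <- y ~ (aN + bN * Tg) *
      (1 - 1 / (1 + exp((dHm * (1 - Tg / Tm) +
                           dCp * ((Tg - Tm) - Tg * log(Tg / Tm))) /
                          (Rgas * Tg)))) +
      (aU + bU * Tg) / (1 + exp((dHm * (1 - Tg / Tm) +
                                   dCp * ((Tg - Tm) - Tg * log(Tg / Tm))) /
                                  (Rgas * Tg)))
  } else {
    form <- y ~ (aN + bN * Tg) *
      (1 - 1 / (1 + exp(dHm * (1 - Tg / Tm) / (Rgas * Tg)))) +
      (aU + bU * Tg) / (1 + exp(dHm * (1 - Tg / Tm) / (Rgas * Tg)))
  }
  ms <- .multistart_nls(form, data = data.frame(Tg = Tg, y = y, Rgas = Rgas),
                        start = start, lower = lower, upper = upper,
                        restarts = restarts)
  .fold_fit_from_nls(ms$fit, "thermal_two_state", curve,
                     n_restarts = ms$n_restarts)
}

# ---- global linkage fitting ------------------------------------------------

# flatten a linkage_params object to a named numeric vector and back
.flatten_linkage <- function(params) {
  out <- c()
  for (nm in c("step_NS", "step_NU")) {
    st <- params[[nm]]
    if (!is.null(st))
      out <- c(out, setNames(c(st$Tm, st$dHm, st$dCp),
                             paste0(nm, c(".Tm", ".dHm", ".dCp"))))
  }
  for (nm in c("assoc_H", "assoc_H2", "bind_P")) {
    st <- params[[nm]]
    if (!is.null(st))
      out <- c(out, setNames(c(st$dG_ref, st$dH_ref, st$dCp),
                             paste0(nm, c(".dG_ref", ".dH_ref", ".dCp"))))
  }
  out
}

.update_linkage <- function(params, values) {
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(params[[parts[1]]]))
      abort(sprintf("Unknown or disabled linkage parameter: %s", nm))
    params[[parts[1]]][[parts[2]]] <- unname(values[[nm]])
  }
  params
}

.linkage_bounds <- function(names) {
  lo <- numeric(length(names)); hi <- numeric(length(names))
  for (i in seq_along(names)) {
    f <- sub("^.*\\.", "", names[i])
    b <- switch(f,
                Tm = c(250, 450), dHm = c(10, 2000), dCp = c(-50, 50),
                dG_ref = c(-500, 50), dH_ref = c(-1000, 1000),
                T_ref = c(250, 450),
                abort(sprintf("No bounds defined for field %s", f)))
    lo[i] <- b[1]; hi[i] <- b[2]
  }
  list(lower = setNames(lo, names), upper = setNames(hi, names))
}

.predict_linkage_series <- function(params, series, basis) {
  out <- numeric(nrow(series))
  key <- paste(series$kind, series$series)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    blk <- series[idx, ]
    if (blk$kind[1] == "melt") {
      if (is.null(basis)) abort("Melt series require a `basis`.")
      st <- solve_species(params, conditions(C_tot = blk$C_tot[1],
                                             T = blk$x,
                                             P_tot = blk$P_tot[1]))
      out[idx] <- .basis_signal(st, basis)
    } else if (blk$kind[1] == "titration") {
      st <- solve_species(params, conditions(C_tot = blk$C_tot[1],
                                             T = blk$T[1], P_tot = blk$x))
      out[idx] <- monomer_fraction(st)
    } else {
      abort(sprintf("Unsupported series kind for global fit: %s",
                    blk$kind[1]))
    }
  }
  out
}

#' Global fit of the linkage model across condition series
#'
#' Jointly fits a shared set of linkage parameters to several observable
#' series (thermal melts at different protein concentrations and/or
#' peptide titrations), freeing only the parameters named in `free`.
#' Separating conformational from association steps requires series that
#' differ in total concentration, and freeing the peptide-binding step
#' requires peptide-titration data; unidentifiable masks are rejected.
#'
#' Optimisation is bounded quasi-Newton (L-BFGS-B) on the residual sum
#' of squares, with optional Latin-hypercube restarts; standard errors
#' come from the numerical Hessian at the optimum (local quadratic
#' approximation).
#'
#' @param series A [curve_table()] stacking the series to fit; columns
#'   `kind` (`"melt"` with `x` = T, or `"titration"` with `x` = P_tot),
#'   `x`, `y`, `C_tot`, `T`, `P_tot`, `series`.
#' @param params Initial [linkage_params()]; fixed parameters keep
#'   these values.
#' @param free Character vector of flattened parameter names to fit,
#'   e.g. `c("step_NS.Tm", "assoc_H.dG_ref")`.
#' @param basis [signal_basis()] used for melt series.
#' @param restarts Latin-hypercube restarts after the supplied start.
#'   Default 5.
#' @return A `fold_fit` (model `"linkage_global"`); `$extra$params`
#'   holds the fitted [linkage_params()] object.
#' @export
fit_linkage_global <- function(series, params, free, basis = signal_basis(),
                               restarts = 5L) {
  stopifnot(inherits(params, "linkage_params"))
  flat <- .flatten_linkage(params)
  bad <- setdiff(free, names(flat))
  if (length(bad))
    abort(sprintf("Unknown/disabled free parameters: %s",
                  paste(bad, collapse = ", ")))
  n_conc <- length(unique(series$C_tot[series$kind == "melt"]))
  if (any(grepl("^assoc_", free)) &&
      n_conc < 2L && !any(series$kind == "titration"))
    abort(paste("Association parameters are unidentifiable from a",
                "single-concentration series: provide >= 2 concentrations."))
  if (any(grepl("^bind_P", free)) && !any(series$kind == "titration") &&
      length(unique(series$P_tot)) < 2L)
    abort("Freeing bind_P requires peptide-titration data.")
  obj <- function(par) {
    p2 <- .update_linkage(params, setNames(par, free))
    pred <- tryCatch(.predict_linkage_series(p2, series, basis),
                     error = function(e) rep(NA_real_, nrow(series)))
    if (anyNA(pred)) return(1e12)
    sum((pred - series$y)^2)
  }
  b <- .linkage_bounds(free)
  run <- function(start) {
    tryCatch(optim(start, obj, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 500, factr = 1e7)),
             error = function(e) NULL)
  }
  best <- run(flat[free])
  n_used <- 0L
  if (restarts > 0L) {
    draws <- lhs::randomLHS(restarts, length(free))
    for (i in seq_len(restarts)) {
      cand_start <- b$lower + draws[i, ] * (b$upper - b$lower)
      # restarts stay near the supplied values for scale parameters
      cand_start <- (cand_start + flat[free]) / 2
      cand <- run(setNames(cand_start, free))
      n_used <- n_used + 1L
      if (!is.null(cand) && (is.null(best) || cand$value < best$value))
        best <- cand
      if (!is.null(best) && best$value < 1e-16) break
    }
  }
  if (is.null(best))
    abort("Global linkage fit failed to converge after multi-start cap.")
  est <- setNames(best$par, free)
  hess <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
  p <- length(free); n <- nrow(series)
  se <- setNames(rep(NA_real_, p), free)
  if (!is.null(hess)) {
    s2 <- best$value / max(n - p, 1)
    cv <- tryCatch(2 * s2 * solve(hess), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) se <- sqrt(diag(cv))
  }
  new_fold_fit("linkage_global", est, se, rss = best$value,
               converged = best$convergence == 0, n_restarts = n_used,
               nobs = n, data = series,
               extra = list(params = .update_linkage(params,
                                                     setNames(est, free))))
}

# ---- recovery studies ------------------------------------------------------

#' Parameter-recovery simulation study
#'
#' Generates `R` replicate synthetic datasets, fits each, and reports
#' per-parameter bias and RMSE against the generating truth. Replicate
#' seeds are drawn deterministically from the master seed, so the whole
#' study is reproducible; fitter failures are counted and reported, not
#' silently dropped.
#'
#' @param generate Function of one argument (an integer seed) returning
#'   a synthetic dataset.
#' @param fit Function mapping that dataset to a `fold_fit` (or a named
#'   numeric vector of estimates).
#' @param true Named numeric vector of generating parameter values;
#'   only these terms are reported.
#' @param R Number of replicates (>= 1; >= 10 recommended for reported
#'   statistics).
#' @param seed Master seed.
#' @return A `recovery_report` tibble: `term`, `true`, `mean`, `bias`,
#'   `rmse`, `sd`, with attributes `R`, `n_fail`, `seed` and the full
#'   per-replicate estimate table in `attr(, "estimates")`.
#' @examples
#' wt <- ci2_fixture("ci2_wt")$chem
#' rep <- recovery_study(
#'   generate = function(s) gen_chem_denaturation(wt, noise = noise_spec(0.02, s)),
#'   fit = fit_lem, true = c(dG0 = wt$dG0, Cm = wt$Cm), R = 10, seed = 1)
#' rep
#' @export
recovery_study <- function(generate, fit, true, R = 100L, seed = 1L) {
  if (R < 1L) abort("`R` must be >= 1.")
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, R))
  rows <- vector("list", R)
  n_fail <- 0L
  for (i in seq_len(R)) {
    est <- tryCatch({
      f <- fit(generate(seeds[i]))
      if (inherits(f, "fold_fit")) coef(f) else f
    }, error = function(e) NULL)
    if (is.null(est)) { n_fail <- n_fail + 1L; next }
    rows[[i]] <- tibble(replicate = i, seed = seeds[i],
                        term = names(est), estimate = unname(est))
  }
  est_tbl <- bind_rows(rows)
  if (nrow(est_tbl) == 0L) abort("Every replicate fit failed.")
  rep_tbl <- est_tbl |>
    filter(.data$term %in% names(true)) |>
    mutate(true = unname(true[.data$term])) |>
    group_by(.data$term) |>
    summarise(true = .data$true[1],
              mean = mean(.data$estimate),
              bias = mean(.data$estimate - .data$true),
              rmse = sqrt(mean((.data$estimate - .data$true)^2)),
              sd = sd(.data$estimate),
              .groups = "drop")
  structure(rep_tbl,
            class = c("recovery_report", class(rep_tbl)),
            R = R, n_fail = n_fail, seed = seed, estimates = est_tbl)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: %d replicates, %d failure(s), seed %d>\n",
              attr(x, "R"), attr(x, "n_fail"), attr(x, "seed")))
  NextMethod()
}

#' One-row summary of a recovery study
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return A tibble with `R`, `n_fail`, `failure_rate`, `seed`.
#' @export
glance.recovery_report <- function(x, ...) {
  tibble(R = attr(x, "R"), n_fail = attr(x, "n_fail"),
         failure_rate = attr(x, "n_fail") / attr(x, "R"),
         seed = attr(x, "seed"))
}
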