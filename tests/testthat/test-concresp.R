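test_that("BMR is one (scaled) MAD above the DMSO median", {
  expect_equal(compute_bmr(c(1, 2, 3, 4, 5), mad_scale_constant = 1)$bmr, 4)
  expect_equal(compute_bmr(c(1, 2, 3, 4, 5))$bmr, 3 + 1.4826)
  expect_warning(b <- compute_bmr(c(2, 2, 2, 2)), "zero MAD")
  expect_equal(b$bmr, 2)
  expect_error(compute_bmr(numeric(0)), "at least 2")
})

test_that("noise-free hill data are recovered within 1% and beat poly1 on AIC", {
  s <- hill_series(tp = 10, ga = 1, p = 2)
  fits <- fit_models(s$conc, s$resp, models = c("constant", "poly1", "hill"))
  h <- fits$hill
  expect_true(h$converged)
  expect_equal(h$par$tp, 10, tolerance = 0.01)
  expect_equal(h$par$ga, 1, tolerance = 0.01)
  expect_equal(h$par$p, 2, tolerance = 0.01)
  expect_lt(h$aic, fits$poly1$aic)
  expect_equal(select_winner(fits)$model, "hill")
})

test_that("AIC selection is an argmin invariant to fitting order", {
  fake <- function(name, aic) structure(list(model = name, converged = TRUE, aic = aic),
                                        class = "cr_fit")
  fits <- list(hill = fake("hill", 10), power = fake("power", 12))
  expect_equal(select_winner(fits)$model, "hill")
  expect_equal(select_winner(rev(fits))$model, "hill")
  # non-converged models never win
  fits$hill$converged <- FALSE
  expect_equal(select_winner(fits)$model, "power")

  s <- hill_series(tp = 8, ga = 0.5, p = 1.5)
  set.seed(1); resp <- s$resp + rnorm(length(s$resp), sd = 0.4)
  f1 <- fit_models(s$conc, resp)
  f2 <- fit_models(s$conc, resp, models = rev(cr_model_names()))
  expect_equal(select_winner(f1)$model, select_winner(f2)$model)
})

test_that("a flat series is won by the constant model", {
  # flat around zero with identical within-concentration spread: no
  # concentration-dependent model can improve the likelihood, so the extra
  # parameters only pay the AIC penalty
  conc <- rep(10^seq(-2, 1.5, by = 0.5), each = 3)
  resp <- rep(c(-0.1, 0, 0.1), 8)
  fits <- fit_models(conc, resp)
  expect_equal(select_winner(fits)$model, "constant")
  expect_equal(fits$constant$aic, 2 * 1 - 2 * fits$constant$loglik)
})

test_that("hitcall is a bounded product and tracks signal strength", {
  set.seed(3)
  conc <- rep(10^seq(-2, 1.5, by = 0.5), each = 3)
  for (top in c(0, 0.5, 10)) {
    resp <- top / (1 + 1 / conc) + rnorm(length(conc), 0, 0.5)
    fits <- fit_models(conc, resp)
    hc <- compute_hitcall(fits, conc, resp, cutoff = 1)
    expect_gte(hc$hitcall, 0); expect_lte(hc$hitcall, 1)
    expect_true(all(c(hc$p1, hc$p2, hc$p3) >= 0 & c(hc$p1, hc$p2, hc$p3) <= 1))
  }
})

test_that("hitcall separates null from strong series in seeded simulations", {
  # null: pure noise around 0 with cutoff 1 sd; strong: top = 10 x cutoff
  conc <- rep(10^seq(-2, 1.5, by = 0.5), each = 3)
  n_sim <- 200
  models <- c("constant", "poly1", "power", "hill", "exp4")
  null_hits <- strong_hits <- logical(n_sim)
  set.seed(42)
  for (i in seq_len(n_sim)) {
    noise <- rnorm(length(conc), 0, 1)
    fits <- fit_models(conc, noise, models = models)
    null_hits[i] <- compute_hitcall(fits, conc, noise, cutoff = 1.5)$hitcall < 0.9
    strong <- 15 / (1 + 1 / conc) + rnorm(length(conc), 0, 1)
    fits2 <- fit_models(conc, strong, models = models)
    strong_hits[i] <- compute_hitcall(fits2, conc, strong, cutoff = 1.5)$hitcall > 0.9
  }
  expect_gte(mean(null_hits), 0.95)
  expect_gte(mean(strong_hits), 0.95)
})

test_that("BMC matches the hill closed form and reports non-crossings", {
  fit <- manual_hill_fit(tp = 10, ga = 1, p = 1)
  # solve 10c/(c+1) = 1  =>  c = 1/9
  r <- compute_bmc(fit, bmr = 1, conc_range = c(0.0316, 100))
  expect_equal(r$bmc, 1 / 9, tolerance = 1e-6)
  expect_true(is.na(r$flag))
  # BMR above the fitted top: no crossing
  r2 <- compute_bmc(fit, bmr = 11, conc_range = c(0.0316, 100))
  expect_true(is.na(r2$bmc))
  expect_equal(r2$flag, "no_crossing")
  # curve already above the BMR at the search floor is flagged
  r3 <- compute_bmc(manual_hill_fit(10, 1e-9, 1), bmr = 1, conc_range = c(0.1, 100))
  expect_equal(r3$flag, "below_search_floor")
})

test_that("doubling concentrations doubles the refitted BMC", {
  s <- hill_series(tp = 10, ga = 1, p = 1.5)
  f1 <- select_winner(fit_models(s$conc, s$resp, models = c("constant", "hill")))
  b1 <- compute_bmc(f1, bmr = 2, conc_range = range(s$conc))$bmc
  f2 <- select_winner(fit_models(2 * s$conc, s$resp, models = c("constant", "hill")))
  b2 <- compute_bmc(f2, bmr = 2, conc_range = range(2 * s$conc))$bmc
  expect_equal(b2 / b1, 2, tolerance = 1e-3)
})

test_that("BMC decreases as implanted potency increases (noise-free)", {
  bmcs <- vapply(c(4, 1, 0.25), function(ga) {
    s <- hill_series(tp = 10, ga = ga, p = 1.5)
    w <- select_winner(fit_models(s$conc, s$resp, models = c("constant", "hill")))
    compute_bmc(w, bmr = 1.5, conc_range = range(s$conc))$bmc
  }, numeric(1))
  expect_true(all(diff(bmcs) < 0))
})

test_that("bootstrap confidence limits are seeded and drop out under >50% misses", {
  s <- hill_series(tp = 10, ga = 1, p = 1.5)
  set.seed(4); resp <- s$resp + rnorm(length(s$resp), sd = 0.5)
  w <- select_winner(fit_models(s$conc, resp, models = c("constant", "hill")))
  ci1 <- bootstrap_bmc_ci(s$conc, resp, w, bmr = 2, conc_range = range(s$conc),
                          n_boot = 60, seed = 11)
  ci2 <- bootstrap_bmc_ci(s$conc, resp, w, bmr = 2, conc_range = range(s$conc),
                          n_boot = 60, seed = 11)
  expect_equal(ci1, ci2)
  expect_true(ci1$bmcl <= ci1$bmcu)
  # a BMR no resample can reach leaves the limits absent
  ci3 <- bootstrap_bmc_ci(s$conc, resp, w, bmr = 500, conc_range = range(s$conc),
                          n_boot = 20, seed = 11)
  expect_true(is.na(ci3$bmcl) && is.na(ci3$bmcu))
  expect_gt(ci3$n_missing, 10)
})

test_that("exclusion rules implement the hitcall/range/CI criteria", {
  res <- data.table::data.table(
    hitcall = c(0.85, 0.95, 0.95, 0.95, 0.95),
    bmc = c(2, 150, 2, NA, 2), bmcl = c(1, 100, NA, NA, 1),
    bmcu = c(4, 200, 4, NA, 4), top_conc = 100)
  out <- apply_exclusion_rules(res)
  expect_equal(out$excluded, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$reason[1:4],
               c("low_hitcall", "above_top_conc", "missing_ci", "no_crossing"))
})

test_that("fit_batch_distances assembles a full result table", {
  # distances with one clearly active and one inert chemical
  set.seed(5)
  conc8 <- 10^seq(1.5, -2, by = -0.5)
  dist <- data.table::rbindlist(list(
    data.table::data.table(plate_id = "P1", well = paste0("A", 1:8),
                           chemical = "DMSO", concentration = 0, role = "vehicle",
                           scope = "global", distance = rnorm(8, 10, 1)),
    data.table::data.table(plate_id = "P1", well = paste0("B", 1:8),
                           chemical = "act", concentration = conc8, role = "test",
                           scope = "global",
                           distance = 10 + 40 / (1 + (1 / conc8)^2) + rnorm(8, 0, 1)),
    data.table::data.table(plate_id = "P1", well = paste0("C", 1:8),
                           chemical = "inert", concentration = conc8, role = "test",
                           scope = "global", distance = rnorm(8, 10, 1))))
  res <- fit_batch_distances(dist, n_boot = 40, seed = 3)
  expect_setequal(res$chemical, c("act", "inert"))
  act <- res[chemical == "act"]
  expect_gt(act$hitcall, 0.9)
  expect_false(act$excluded)
  expect_true(act$bmc > min(conc8) / 100 && act$bmc < max(conc8))
  expect_true(res[chemical == "inert", excluded])
  # reported AIC satisfies its definition for the winner
  expect_equal(act$aic, 2 * fit_models(conc8, rep(0, 8),
                                       models = act$model)[[1]]$npar - 2 * act$loglik)
})
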