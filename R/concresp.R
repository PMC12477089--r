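#' Benchmark response from vehicle-well distances
#'
#' The BMR is one MAD above the median Mahalanobis distance of the batch's
#' DMSO wells: `bmr = median(D) + mad_scale_constant * rawMAD(D)`. When the
#' MAD degenerates to zero the BMR equals the median, with a warning.
#'
#' @param dmso_distances Numeric vector of vehicle-well distances.
#' @param mad_scale_constant MAD multiplier, default 1.4826 (same knob as the
#'   normalization MAD).
#' @return list `bmr`, `dmso_median`, `dmso_mad` (raw MAD).
#' @export
compute_bmr <- function(dmso_distances, mad_scale_constant = 1.4826) {
  if (length(dmso_distances) < 2L) stop("need at least 2 DMSO distances for the BMR")
  med <- median(dmso_distances)
  raw_mad <- median(abs(dmso_distances - med))
  if (raw_mad == 0) {
    warning("zero MAD of DMSO distances; BMR set to the median")
  }
  list(bmr = med + mad_scale_constant * raw_mad, dmso_median = med, dmso_mad = raw_mad)
}

# Delta-method SE of the signed top of a fit, from the numerical Hessian of
# the negative log-likelihood at the optimum. Falls back to the fitted sigma
# when the Hessian is not usable (top then effectively untestable).
top_se <- function(fit, x, y) {
  if (!fit$converged || is.null(fit$u) || length(fit$u) < 2L) return(fit$sigma)
  def <- cr_model_defs()[[fit$model]]
  s_min <- fit$s_min
  nll <- function(u) {
    np <- length(def$pars)
    p <- def$untrans(u[seq_len(np)])
    sigma <- s_min + exp(u[np + 1L])
    r <- y - def$fun(p, x)
    ll <- cr_loglik(r, sigma, fit$error_model)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  topf <- function(u) {
    p <- def$untrans(u[seq_along(def$pars)])
    grid <- 10^seq(log10(fit$x_range[1]), log10(fit$x_range[2]), length.out = 200)
    fx <- def$fun(p, grid)
    fx[which.max(abs(fx))]
  }
  se <- tryCatch({
    H <- optimHess(fit$u, nll)
    V <- solve(H)
    eps <- 1e-4
    g <- vapply(seq_along(fit$u), function(i) {
      up <- fit$u; up[i] <- up[i] + eps
      dn <- fit$u; dn[i] <- dn[i] - eps
      (topf(up) - topf(dn)) / (2 * eps)
    }, numeric(1))
    v <- drop(t(g) %*% V %*% g)
    if (!is.finite(v) || v <= 0) stop("bad variance")
    sqrt(v)
  }, error = function(e) fit$sigma)
  max(se, 1e-12)
}

#' Continuous hitcall for a concentration series
#'
#' `hitcall = P1 * P2 * P3`, each a probability in `[0, 1]`:
#' * `P1` - at least one concentration's median response exceeds the cutoff:
#'   `1 - prod(pt((cutoff - med_i) / (sigma / sqrt(n_i)), df = 4))` using the
#'   winning fit's error scale.
#' * `P2` - the winning fit's top exceeds the cutoff, via a delta-method
#'   standard error of the top on the t(4) scale.
#' * `P3` - one minus the Akaike weight of the constant model against the
#'   best converged non-constant model.
#'
#' @param fits List of `cr_fit`s (must include `constant`).
#' @param conc,resp The fitted series.
#' @param cutoff Response threshold, on the same (centered) scale as `resp`;
#'   normally `bmr - median(DMSO distances)`.
#' @param winner Optional pre-selected winning fit.
#' @return list `hitcall`, `p1`, `p2`, `p3`, `winner` (model name).
#' @export
compute_hitcall <- function(fits, conc, resp, cutoff, winner = NULL) {
  if (is.null(winner)) winner <- select_winner(fits)
  sigma <- if (is.finite(winner$sigma)) winner$sigma else sd(resp)
  meds <- tapply(resp, conc, median)
  ns <- tapply(resp, conc, length)
  se_med <- sigma / sqrt(as.numeric(ns))
  p1 <- 1 - prod(pt((cutoff - as.numeric(meds)) / se_med, df = 4))
  top <- if (winner$model == "constant") 0 else fit_top(winner)
  se_t <- top_se(winner, conc, resp)
  p2 <- 1 - pt((cutoff - top) / se_t, df = 4)
  aic_const <- fits[["constant"]]$aic
  nc <- fits[setdiff(names(fits), "constant")]
  nc_aic <- vapply(nc, function(f) if (isTRUE(f$converged)) f$aic else Inf, numeric(1))
  if (all(!is.finite(nc_aic))) {
    p3 <- 0
  } else {
    a2 <- min(nc_aic)
    m <- min(aic_const, a2)
    w_const <- exp(-0.5 * (aic_const - m)) /
      (exp(-0.5 * (aic_const - m)) + exp(-0.5 * (a2 - m)))
    p3 <- 1 - w_const
  }
  hc <- min(max(p1 * p2 * p3, 0), 1)
  list(hitcall = hc, p1 = unname(p1), p2 = unname(p2), p3 = unname(p3),
       winner = winner$model)
}

#' Benchmark concentration: first crossing of the fitted curve with the BMR
#'
#' The fitted curve is scanned on a fine logarithmic grid from
#' `conc_range[1] / floor_div` (search floor) to `conc_range[2]`, and the
#' smallest concentration where it reaches `bmr` is refined by root finding
#' (relative tolerance 1e-6). A curve already above the BMR at the floor is
#' reported at the floor with flag `below_search_floor`; a curve that never
#' crosses yields an absent BMC with reason `no_crossing`.
#'
#' @param fit A `cr_fit` (the winning model).
#' @param bmr Benchmark response on the same scale the model was fitted on.
#' @param conc_range `c(lowest, highest)` tested concentration.
#' @param floor_div Search-floor divisor for the lowest concentration.
#' @param n_grid Grid size for the crossing scan.
#' @return list `bmc` (`NA` if absent), `flag` (`NA`, `"below_search_floor"`
#'   or `"no_crossing"`).
#' @export
compute_bmc <- function(fit, bmr, conc_range, floor_div = 100, n_grid = 1000L) {
  lo <- conc_range[1] / floor_div
  hi <- conc_range[2]
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  fx <- predict(fit, grid) - bmr
  if (!any(is.finite(fx))) return(list(bmc = NA_real_, flag = "no_crossing"))
  if (fx[1] >= 0) return(list(bmc = lo, flag = "below_search_floor"))
  cross <- which(fx >= 0)[1]
  if (is.na(cross)) return(list(bmc = NA_real_, flag = "no_crossing"))
  root <- uniroot(function(c) predict(fit, c) - bmr,
                  lower = grid[cross - 1L], upper = grid[cross],
                  tol = 1e-7 * grid[cross])
  list(bmc = root$root, flag = NA_character_)
}

#' Bootstrap confidence limits for the BMC
#'
#' Nonparametric bootstrap over wells within concentration groups: each
#' resample redraws wells with replacement inside every concentration, refits
#' the winning model (warm-started at the original optimum) and recomputes
#' the BMC. Resamples without a BMR crossing contribute missing values; if
#' more than half are missing the limits are reported absent (triggering the
#' missing-CI exclusion downstream). Percentile 95% limits otherwise.
#'
#' @param conc,resp Series the winner was fitted on.
#' @param winner The winning `cr_fit`.
#' @param bmr,conc_range,floor_div As in [compute_bmc()].
#' @param n_boot Number of resamples (default 500).
#' @param seed Integer seed for the resampling RNG.
#' @return list `bmcl`, `bmcu` (`NA` when absent), `n_missing`, `n_boot`.
#' @export
bootstrap_bmc_ci <- function(conc, resp, winner, bmr, conc_range,
                             floor_div = 100, n_boot = 500L, seed = 1L) {
  if (winner$model == "constant" || n_boot < 1L) {
    return(list(bmcl = NA_real_, bmcu = NA_real_, n_missing = n_boot, n_boot = n_boot))
  }
  def <- cr_model_defs()[[winner$model]]
  groups <- split(seq_along(conc), conc)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  bmcs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g) g[sample.int(length(g), length(g), replace = TRUE)]),
                  use.names = FALSE)
    xb <- conc[idx]; yb <- resp[idx]
    fb <- tryCatch(refit_warm(winner, xb, yb), error = function(e) NULL)
    if (is.null(fb) || !fb$converged) next
    r <- compute_bmc(fb, bmr, conc_range, floor_div, n_grid = 400L)
    if (!is.na(r$bmc)) bmcs[b] <- r$bmc
  }
  n_missing <- sum(is.na(bmcs))
  if (n_missing > n_boot / 2) {
    return(list(bmcl = NA_real_, bmcu = NA_real_, n_missing = n_missing, n_boot = n_boot))
  }
  q <- quantile(bmcs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(bmcl = q[1], bmcu = q[2], n_missing = n_missing, n_boot = n_boot)
}

# Refit one model warm-started at a previous optimum (used by the bootstrap).
refit_warm <- function(fit, x, y) {
  def <- cr_model_defs()[[fit$model]]
  s_min <- fit$s_min
  nll <- function(u) {
    np <- length(def$pars)
    p <- def$untrans(u[seq_len(np)])
    sigma <- s_min + exp(u[np + 1L])
    r <- y - def$fun(p, x)
    if (any(!is.finite(r))) return(1e10)
    ll <- cr_loglik(r, sigma, fit$error_model)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- optim(fit$u, nll, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-9))
  np <- length(def$pars)
  p <- lapply(def$untrans(opt$par[seq_len(np)]), unname)
  structure(list(model = fit$model, converged = is.finite(opt$value),
                 par = p, sigma = s_min + exp(opt$par[np + 1L]),
                 loglik = -opt$value, aic = 2 * fit$npar + 2 * opt$value,
                 npar = fit$npar, u = opt$par, fun = def$fun, s_min = s_min,
                 error_model = fit$error_model, x_range = fit$x_range),
            class = "cr_fit")
}

#' Apply the BMC exclusion rules
#'
#' A BMC is excluded when the hitcall is below 0.9 (`low_hitcall`), when it
#' exceeds the highest tested concentration (`above_top_conc`), when either
#' confidence limit is absent (`missing_ci`), or when no BMR crossing exists
#' (`no_crossing`). Reasons are assigned in that order.
#'
#' @param results data.table with columns `hitcall`, `bmc`, `bmcl`, `bmcu`,
#'   `top_conc` (one row per chemical x scope).
#' @param hitcall_threshold Default 0.9.
#' @return The table with logical `excluded` and character `reason` columns.
#' @export
apply_exclusion_rules <- function(results, hitcall_threshold = 0.9) {
  results <- as.data.table(results)
  results[, excluded := FALSE]
  results[, reason := NA_character_]
  results[hitcall < hitcall_threshold, c("excluded", "reason") := .(TRUE, "low_hitcall")]
  results[!excluded & !is.na(bmc) & bmc > top_conc,
          c("excluded", "reason") := .(TRUE, "above_top_conc")]
  results[!excluded & is.na(bmc), c("excluded", "reason") := .(TRUE, "no_crossing")]
  results[!excluded & (is.na(bmcl) | is.na(bmcu)),
          c("excluded", "reason") := .(TRUE, "missing_ci")]
  results[]
}

#' Concentration-response analysis of a batch's distance results
#'
#' Derives the BMR from the vehicle-well distances, then for every chemical
#' (all non-vehicle series) fits the model family to the vehicle-median-
#' centered distances, selects the AIC winner, computes the continuous
#' hitcall, the BMC (crossing of the centered curve with
#' `bmr - median(DMSO)`), bootstrap confidence limits, and the exclusion
#' flags.
#'
#' @param distances A `distance_result` from [mahalanobis_distances()].
#' @param mad_scale_constant MAD multiplier for the BMR.
#' @param n_boot Bootstrap resamples for the confidence limits (0 disables;
#'   limits are then absent and rows fail the missing-CI rule).
#' @param seed Seed for the bootstrap.
#' @param models,error_model Passed to [fit_models()].
#' @param floor_div BMC search floor divisor.
#' @return A `data.table`, one row per chemical: winning model, JSON-encoded
#'   parameters, aic, hitcall, bmr, bmc, bmcl, bmcu, excluded, reason.
#' @export
fit_batch_distances <- function(distances, mad_scale_constant = 1.4826,
                                n_boot = 500L, seed = 1L,
                                models = cr_model_names(), error_model = "t4",
                                floor_div = 100) {
  scope <- distances$scope[1]
  dmso <- distances[role == "vehicle", distance]
  bmr_info <- compute_bmr(dmso, mad_scale_constant)
  cutoff <- bmr_info$bmr - bmr_info$dmso_median
  chems <- unique(distances[role != "vehicle" & concentration > 0, chemical])
  rows <- list()
  for (i in seq_along(chems)) {
    ch <- chems[i]
    ser <- distances[chemical == ch & concentration > 0]
    if (length(unique(ser$concentration)) < 2L) next
    conc <- ser$concentration
    resp <- ser$distance - bmr_info$dmso_median
    fits <- fit_models(conc, resp, models, error_model)
    winner <- select_winner(fits)
    hc <- compute_hitcall(fits, conc, resp, cutoff, winner)
    cr <- range(conc)
    bmc <- compute_bmc(winner, cutoff, cr, floor_div)
    ci <- bootstrap_bmc_ci(conc, resp, winner, cutoff, cr, floor_div,
                           n_boot = n_boot, seed = seed + i)
    rows[[ch]] <- data.table(
      chemical = ch, scope = scope, model = winner$model,
      params = as.character(jsonlite::toJSON(winner$par, digits = NA, auto_unbox = TRUE)),
      aic = winner$aic, loglik = winner$loglik, sigma = winner$sigma,
      hitcall = hc$hitcall, p1 = hc$p1, p2 = hc$p2, p3 = hc$p3,
      bmr = bmr_info$bmr, dmso_median = bmr_info$dmso_median,
      bmc = bmc$bmc, bmc_flag = bmc$flag, bmcl = ci$bmcl, bmcu = ci$bmcu,
      top_conc = cr[2], min_conc = cr[1])
  }
  if (!length(rows)) stop("no fittable concentration series in distance table")
  apply_exclusion_rules(rbindlist(rows))
}
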