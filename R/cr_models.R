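# Concentration-response model family (tcplfit2 semantics, x = concentration):
#   constant  f = 0
#   poly1     f = a*x
#   poly2     f = a*(x/b + (x/b)^2)
#   power     f = a*x^p
#   hill      f = tp / (1 + (ga/x)^p)
#   gain_loss f = tp / ((1 + (ga/x)^p) * (1 + (x/la)^q))
#   exp2      f = a*(exp(x/b) - 1)
#   exp3      f = a*(exp((x/b)^p) - 1)
#   exp4      f = tp*(1 - 2^(-x/ga))
#   exp5      f = tp*(1 - 2^(-(x/ga)^p))
# Exponents p, q are bounded to [0.3, 8]; scale parameters are positive.

safe_exp <- function(z) exp(pmin(z, 700))

P_RANGE <- c(0.3, 8)

to_range <- function(u, lo = P_RANGE[1], hi = P_RANGE[2]) lo + (hi - lo) / (1 + exp(-u))
from_range <- function(p, lo = P_RANGE[1], hi = P_RANGE[2]) {
  p <- pmin(pmax(p, lo + 1e-9), hi - 1e-9)
  log((p - lo) / (hi - p))
}

# Each model: natural parameter names, map from unconstrained vector u to a
# named list, inverse map for starts, and the mean function.
cr_model_defs <- function() {
  list(
    constant = list(
      pars = character(0),
      fun = function(p, x) rep(0, length(x)),
      untrans = function(u) list(),
      trans = function(p) numeric(0)
    ),
    poly1 = list(
      pars = "a",
      fun = function(p, x) p$a * x,
      untrans = function(u) list(a = u[1]),
      trans = function(p) p$a
    ),
    poly2 = list(
      pars = c("a", "b"),
      fun = function(p, x) p$a * (x / p$b + (x / p$b)^2),
      untrans = function(u) list(a = u[1], b = exp(u[2])),
      trans = function(p) c(p$a, log(p$b))
    ),
    power = list(
      pars = c("a", "p"),
      fun = function(p, x) p$a * x^p$p,
      untrans = function(u) list(a = u[1], p = to_range(u[2])),
      trans = function(p) c(p$a, from_range(p$p))
    ),
    hill = list(
      pars = c("tp", "ga", "p"),
      fun = function(p, x) p$tp / (1 + (p$ga / x)^p$p),
      untrans = function(u) list(tp = u[1], ga = exp(u[2]), p = to_range(u[3])),
      trans = function(p) c(p$tp, log(p$ga), from_range(p$p))
    ),
    gain_loss = list(
      pars = c("tp", "ga", "p", "la", "q"),
      fun = function(p, x) p$tp / ((1 + (p$ga / x)^p$p) * (1 + (x / p$la)^p$q)),
      untrans = function(u) list(tp = u[1], ga = exp(u[2]), p = to_range(u[3]),
                                 la = exp(u[4]), q = to_range(u[5])),
      trans = function(p) c(p$tp, log(p$ga), from_range(p$p), log(p$la), from_range(p$q))
    ),
    exp2 = list(
      pars = c("a", "b"),
      fun = function(p, x) p$a * (safe_exp(x / p$b) - 1),
      untrans = function(u) list(a = u[1], b = exp(u[2])),
      trans = function(p) c(p$a, log(p$b))
    ),
    exp3 = list(
      pars = c("a", "b", "p"),
      fun = function(p, x) p$a * (safe_exp((x / p$b)^p$p) - 1),
      untrans = function(u) list(a = u[1], b = exp(u[2]), p = to_range(u[3])),
      trans = function(p) c(p$a, log(p$b), from_range(p$p))
    ),
    exp4 = list(
      pars = c("tp", "ga"),
      fun = function(p, x) p$tp * (1 - 2^(-x / p$ga)),
      untrans = function(u) list(tp = u[1], ga = exp(u[2])),
      trans = function(p) c(p$tp, log(p$ga))
    ),
    exp5 = list(
      pars = c("tp", "ga", "p"),
      fun = function(p, x) p$tp * (1 - 2^(-(x / p$ga)^p$p)),
      untrans = function(u) list(tp = u[1], ga = exp(u[2]), p = to_range(u[3])),
      trans = function(p) c(p$tp, log(p$ga), from_range(p$p))
    )
  )
}

#' Names of the concentration-response model family
#' @return Character vector of the ten model names.
#' @export
cr_model_names <- function() names(cr_model_defs())

# Robust likelihood: residuals r = y - f(x), r/sigma ~ Student-t with 4 df
# (Gaussian available). Returns the log-likelihood.
cr_loglik <- function(r, sigma, error_model = "t4") {
  if (error_model == "t4") {
    sum(dt(r / sigma, df = 4, log = TRUE) - log(sigma))
  } else {
    sum(stats::dnorm(r, sd = sigma, log = TRUE))
  }
}

# Heuristic starting values on the natural scale for one model.
cr_starts <- function(name, x, y) {
  cmax <- max(x); cmin <- min(x)
  med_by_conc <- tapply(y, x, median)
  top_med <- med_by_conc[[length(med_by_conc)]]
  big <- med_by_conc[which.max(abs(med_by_conc))]
  rmax <- max(abs(y), 1e-6)
  gmid <- sqrt(cmin * cmax)
  s <- switch(name,
    constant = list(list()),
    poly1 = list(list(a = big / cmax), list(a = -big / cmax)),
    poly2 = list(list(a = big / 2, b = cmax), list(a = big, b = gmid)),
    power = list(list(a = big / cmax, p = 1), list(a = big / cmax^0.5, p = 0.5)),
    hill = list(list(tp = big, ga = gmid, p = 1.2),
                list(tp = top_med, ga = cmax / 10, p = 2),
                list(tp = big, ga = cmin * 3, p = 0.8)),
    gain_loss = list(list(tp = big, ga = gmid, p = 1.2, la = cmax * 10, q = 2),
                     list(tp = big, ga = cmin * 3, p = 1.2, la = cmax, q = 2)),
    exp2 = list(list(a = big / (exp(1) - 1), b = cmax), list(a = rmax / 100, b = cmax / 3)),
    exp3 = list(list(a = big / (exp(1) - 1), b = cmax, p = 1),
                list(a = rmax / 100, b = cmax / 2, p = 2)),
    exp4 = list(list(tp = big, ga = gmid), list(tp = top_med, ga = cmax / 5)),
    exp5 = list(list(tp = big, ga = gmid, p = 1.2), list(tp = top_med, ga = cmax / 5, p = 3)),
    stop("unknown model: ", name)
  )
  s
}

# Fit one model by maximum likelihood; returns a cr_fit list.
fit_one_model <- function(name, x, y, error_model = "t4") {
  def <- cr_model_defs()[[name]]
  scale_y <- max(sd(y), 1e-6 * max(abs(y), 1), 1e-12)
  s_min <- 1e-6 * scale_y
  nll <- function(u) {
    np <- length(def$pars)
    p <- def$untrans(u[seq_len(np)])
    sigma <- s_min + exp(u[np + 1L])
    r <- y - def$fun(p, x)
    if (any(!is.finite(r))) return(1e10)
    ll <- cr_loglik(r, sigma, error_model)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- cr_starts(name, x, y)
  best <- NULL
  for (st in starts) {
    u0 <- c(def$trans(st), log(scale_y / 2))
    opt <- tryCatch(
      if (length(u0) == 1L) {
        optim(u0, nll, method = "Brent", lower = u0 - 30, upper = u0 + 30)
      } else {
        optim(u0, nll, method = "Nelder-Mead",
              control = list(maxit = 800, reltol = 1e-10))
      },
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  npar <- length(def$pars) + 1L  # + sigma
  if (is.null(best)) {
    return(structure(list(model = name, converged = FALSE, par = NULL,
                          sigma = NA_real_, loglik = -Inf, aic = Inf,
                          npar = npar, u = NULL, fun = def$fun),
                     class = "cr_fit"))
  }
  np <- length(def$pars)
  p <- lapply(def$untrans(best$par[seq_len(np)]), unname)
  sigma <- s_min + exp(best$par[np + 1L])
  ll <- -best$value
  structure(list(model = name, converged = TRUE, par = p, sigma = sigma,
                 loglik = ll, aic = 2 * npar - 2 * ll, npar = npar,
                 u = best$par, fun = def$fun, s_min = s_min,
                 error_model = error_model, x_range = range(x)),
            class = "cr_fit")
}

#' Predict the fitted mean response of a model fit
#' @param object A `cr_fit` from [fit_models()].
#' @param newdata Concentrations at which to evaluate the curve.
#' @param ... Unused.
#' @export
predict.cr_fit <- function(object, newdata, ...) {
  object$fun(object$par, newdata)
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf("<cr_fit %s> converged=%s aic=%.3f pars: %s sigma=%.4g\n",
              x$model, x$converged, x$aic,
              paste(sprintf("%s=%.4g", names(x$par), unlist(x$par)), collapse = " "),
              x$sigma))
  invisible(x)
}

# Signed top: fitted value of largest magnitude over the tested range.
fit_top <- function(fit, conc_range = fit$x_range) {
  grid <- 10^seq(log10(conc_range[1]), log10(conc_range[2]), length.out = 200)
  fx <- predict(fit, grid)
  fx[which.max(abs(fx))]
}

#' Fit the full concentration-response model family
#'
#' Each model is fitted by maximum likelihood under a Student-t (4 df) error
#' model with fitted scale (Gaussian optional); multiple heuristic starting
#' points are tried per model and the best optimum kept. Non-converged models
#' are flagged and carry infinite AIC so they never win selection.
#'
#' @param conc Concentrations (micromolar, > 0), one per well.
#' @param resp Responses (here: vehicle-median-centered Mahalanobis
#'   distances), same length.
#' @param models Subset of [cr_model_names()] to fit.
#' @param error_model `"t4"` (default) or `"gaussian"`.
#' @return Named list of `cr_fit` objects.
#' @export
fit_models <- function(conc, resp, models = cr_model_names(), error_model = "t4") {
  stopifnot(length(conc) == length(resp), all(conc > 0))
  if (length(unique(conc)) < 2L) stop("need at least 2 distinct concentrations")
  fits <- lapply(models, fit_one_model, x = conc, y = resp, error_model = error_model)
  names(fits) <- models
  if (all(vapply(fits, function(f) !f$converged, logical(1)))) {
    stop("all concentration-response models failed to converge")
  }
  fits
}

#' Select the winning model by AIC
#'
#' @param fits List of `cr_fit`s from [fit_models()].
#' @return The converged `cr_fit` with the lowest AIC (ties broken by the
#'   fixed family order, so selection is invariant to fitting order).
#' @export
select_winner <- function(fits) {
  fits <- fits[order(match(names(fits), cr_model_names()))]
  aics <- vapply(fits, function(f) if (isTRUE(f$converged)) f$aic else Inf, numeric(1))
  fits[[which.min(aics)]]
}
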