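# Analytic ("no pipeline code") oracle for the true BMC of an implanted
# chemical. The expected generated data are pushed through the normalization
# and distance geometry in closed form:
#
# * The well median of n cells with cell-level SD `noise` has sampling SD
#   sqrt(pi/(2 n)) * noise (asymptotic normal-median variance), so the
#   DMSO-SD scaling divides expected feature shifts by
#   sd_f = sqrt(pi/2 * noise^2 * mean(1/n_veh) + var(density shifts)).
# * Well-median correlation within a category is (2/pi) * asin(rho)
#   (asymptotic correlation of sample medians of equicorrelated normals).
# * Squared Mahalanobis distance is affine invariant, so PCA (which retains
#   ~all variance) can be bypassed: with S = cov of expected well profiles
#   plus the average null covariance, the expected distance elevation of a
#   well with expected normalized shift s is s' S^{-1} s, and the null
#   distances are approximately a Satterthwaite-scaled chi-square with
#   mean tr(S^{-1} Vbar) and variance 2 tr((S^{-1} Vbar)^2).
# * The benchmark response is median + mad_scale_constant * MAD of that null
#   distribution; the oracle BMC is the bisection root of
#   elevation(c) = BMR - median on a fine log grid.

# median and raw MAD of a * chisq(nu)
scaled_chisq_median_mad <- function(a, nu) {
  med <- a * qchisq(0.5, nu)
  g <- function(t) {
    pchisq((med + t) / a, nu) - pchisq(max(med - t, 0) / a, nu) - 0.5
  }
  upper <- a * qchisq(0.9999, nu)
  mad_raw <- uniroot(g, lower = 1e-12, upper = upper, tol = 1e-10)$root
  list(median = med, mad = mad_raw)
}

# Shared geometry of a simulated batch: expected profiles, S inverse, null
# distance distribution and the BMR excess threshold.
oracle_geometry <- function(config, params = norm_params()) {
  F <- config$n_features
  catalog <- synthetic_catalog(config)
  cat_of_feature <- as.integer(sub("cat", "", catalog$category))
  wells <- rbindlist(lapply(seq_len(config$plates_per_batch),
                            function(p) synthetic_plate_layout(config, p)))
  # expected QC: drop wells failing the count rules in expectation
  med_veh <- median(wells[role == "vehicle", mu])
  wells <- wells[mu >= params$min_cells &
                   (1 - mu / med_veh) <= params$max_count_reduction]
  veh <- wells[role == "vehicle"]
  noise <- config$noise
  dens <- config$density_beta * log(wells$mu / config$mean_cells)
  dens_veh <- dens[wells$role == "vehicle"]
  sd_f2 <- (pi / 2) * noise^2 * mean(1 / veh$mu) +
    (if (length(dens_veh) > 1) var(dens_veh) else 0)
  sd_f <- sqrt(sd_f2)
  # expected normalized profiles m_w (wells x F)
  tr <- config$chemicals
  M <- matrix(0, nrow(wells), F)
  for (i in seq_len(nrow(tr))) {
    if (tr$E[i] == 0 || tr$affected_categories[i] == "") next
    cats <- as.integer(strsplit(tr$affected_categories[i], ",")[[1]])
    fidx <- which(cat_of_feature %in% cats)
    widx <- which(wells$chemical == tr$chemical[i] & wells$concentration > 0)
    amp <- tr$E[i] * hill_frac(wells$concentration[widx], tr$ac50[i], tr$hill_h[i])
    M[widx, fidx] <- M[widx, fidx] + amp
  }
  M <- (M + matrix(dens, nrow(wells), F)) / sd_f
  mu_ref <- colMeans(M[wells$role == "vehicle", , drop = FALSE])
  # null well-median correlation structure
  r_med <- (2 / pi) * asin(config$rho)
  R <- matrix(0, F, F)
  same_cat <- outer(cat_of_feature, cat_of_feature, "==")
  R[same_cat] <- r_med
  diag(R) <- 1
  v_w <- (pi / (2 * wells$mu)) * noise^2 / sd_f2
  S <- cov(M) + mean(v_w) * R
  Sinv <- solve(S)
  A <- Sinv %*% (mean(v_w[wells$role == "vehicle"]) * R)
  muD <- sum(diag(A))
  varD <- 2 * sum(A * t(A))
  a <- varD / (2 * muD)
  nu <- 2 * muD^2 / varD
  nd <- scaled_chisq_median_mad(a, nu)
  list(wells = wells, sd_f = sd_f, Sinv = Sinv, mu_ref = mu_ref,
       cat_of_feature = cat_of_feature,
       null_median = nd$median, null_mad = nd$mad,
       threshold = params$mad_scale_constant * nd$mad,
       dens_fun = function(c_mu) config$density_beta * log(c_mu / config$mean_cells))
}

# expected distance elevation of a chemical's well at concentration c,
# including the row-coupled density shift of its position.
oracle_elevation <- function(geom, config, chem_row, conc) {
  F <- config$n_features
  cats <- if (chem_row$affected_categories == "") integer(0) else
    as.integer(strsplit(chem_row$affected_categories, ",")[[1]])
  fidx <- which(geom$cat_of_feature %in% cats)
  # continuous row position: top concentration sits in row A
  j <- pmin(pmax(1 + 2 * log10(chem_row$top_conc / conc), 1), 8)
  surv <- if (!is.na(chem_row$tox_ec50)) {
    1 / (1 + (conc / chem_row$tox_ec50)^chem_row$tox_h)
  } else 1
  mu_c <- config$mean_cells * config$row_gradient^(j - 1) * surv
  vapply(seq_along(conc), function(i) {
    s <- rep(geom$dens_fun(mu_c[i]), F)
    if (length(fidx) && chem_row$E > 0) {
      s[fidx] <- s[fidx] + chem_row$E * hill_frac(conc[i], chem_row$ac50, chem_row$hill_h)
    }
    s <- s / geom$sd_f - geom$mu_ref
    drop(t(s) %*% geom$Sinv %*% s)
  }, numeric(1))
}

#' Analytic oracle BMC for implanted chemicals
#'
#' Computes, for every chemical of a simulation's truth table, the
#' concentration at which the expected (noise-free) Mahalanobis-distance
#' elevation crosses the analytic benchmark response, using closed-form
#' normalization/distance geometry and bisection on a fine logarithmic grid.
#' The computation deliberately bypasses the production pipeline (no
#' normalization, PCA or fitting code is reused) so the two can be compared
#' as independent implementations.
#'
#' @param config A [sim_config()] (carries the truth table).
#' @param params [norm_params()] in force for the pipeline being checked.
#' @param n_grid Grid size for the crossing scan (>= 500).
#' @param floor_div Search floor divisor below the lowest tested
#'   concentration, matching the pipeline's BMC search floor.
#' @return data.table `chemical, role, oracle_bmc, threshold, flag`;
#'   `oracle_bmc` is `NA` for chemicals whose curve never crosses.
#' @export
oracle_bmc <- function(config, params = norm_params(), n_grid = 500L,
                       floor_div = 100) {
  geom <- oracle_geometry(config, params)
  tr <- config$chemicals
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    ch <- tr[i]
    if (ch$role == "vehicle") next
    lowest <- ch$top_conc * 10^(-3.5)
    lo <- lowest / floor_div
    hi <- ch$top_conc
    bmc <- NA_real_
    flag <- NA_character_
    {
      # all non-vehicle chemicals are scanned: even implanted-inert series can
      # elevate the expected distance via the density-morphology coupling
      # (e.g. cytotoxic controls), and the oracle must say so
      grid <- 10^seq(log10(lo), log10(hi), length.out = max(n_grid, 500L))
      ex <- oracle_elevation(geom, config, ch, grid) - geom$threshold
      if (ex[1] >= 0) {
        bmc <- lo
        flag <- "below_search_floor"
      } else if (all(ex < 0)) {
        flag <- "no_crossing"
      } else {
        k <- which(ex >= 0)[1]
        f <- function(cc) oracle_elevation(geom, config, ch, cc) - geom$threshold
        # bisection to relative tolerance 1e-6
        a <- grid[k - 1L]; b <- grid[k]
        while ((b - a) / b > 1e-6) {
          m <- sqrt(a * b)
          if (f(m) >= 0) b <- m else a <- m
        }
        bmc <- sqrt(a * b)
      }
    }
    out[[i]] <- data.table(chemical = ch$chemical, role = ch$role,
                           oracle_bmc = bmc, threshold = geom$threshold,
                           flag = flag)
  }
  rbindlist(out)
}
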