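#' Empirical semivariogram of a site variable
#'
#' Semivariance `gamma(h) = mean((z_i - z_j)^2) / 2` over site pairs binned
#' by separation distance. Bins with no pairs are omitted.
#'
#' @param coords site coordinates (`x`,`y` planar km or `lon`,`lat`).
#' @param values site values (working scale).
#' @param n_bins number of equal-width lag bins.
#' @param max_lag largest lag considered; default half the maximum
#'   inter-site distance (the usual reliability cutoff).
#' @param coord_mode `"planar"` or `"lonlat"`.
#' @return data.frame of class `empirical_variogram` with columns `lag`
#'   (bin midpoint), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(coords, values, n_bins = 15, max_lag = NULL,
                                coord_mode = c("planar", "lonlat")) {
  coord_mode <- match.arg(coord_mode)
  D <- pair_distances(coords, coord_mode)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 sites")
  iu <- which(upper.tri(D))
  h <- D[iu]
  if (all(h == 0)) stop("all sites are coincident")
  if (is.null(max_lag)) max_lag <- max(h) / 2
  g <- (outer(values, values, "-")^2 / 2)[iu]
  keep <- h <= max_lag & h > 0
  h <- h[keep]; g <- g[keep]
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    data.frame(lag = (breaks[b] + breaks[b + 1]) / 2,
               gamma = mean(g[sel]), n_pairs = sum(sel))
  }))
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

# Model semivariance for the supported families.
variogram_gamma <- function(h, nugget, sill, range, family) {
  nugget + sill * (1 - cov_family_rho(h, range, family))
}

#' Fit a theoretical variogram model
#'
#' Weighted least squares over (nugget, sill, range) with Cressie-style
#' weights `n_pairs / gamma_model^2`, parameters bounded nonnegative. On
#' optimizer failure a coarse grid search is used and flagged.
#'
#' @param empirical an [empirical_variogram].
#' @param family covariance family.
#' @return list of class `variogram_model`: `nugget`, `sill`, `range`,
#'   `family`, `empirical`, `converged`, `objective`.
#' @export
fit_variogram <- function(empirical, family = c("exponential", "spherical",
                                                "gaussian")) {
  family <- match.arg(family)
  emp <- as.data.frame(empirical)
  if (nrow(emp) < 3L) stop("need at least 3 nonempty variogram bins")
  h <- emp$lag; g <- emp$gamma; npair <- emp$n_pairs
  obj <- function(par) {
    gm <- variogram_gamma(h, par[1], par[2], par[3], family)
    gm <- pmax(gm, 1e-10)
    sum(npair * (g - gm)^2 / gm^2)
  }
  gmax <- max(g); hmax <- max(h)
  start <- c(nugget = max(min(g), 1e-6 * gmax),
             sill = max(gmax - min(g), 1e-6 * gmax),
             range = hmax / 3)
  lower <- c(0, 0, hmax / 1e4)
  upper <- c(2 * gmax, 5 * gmax, 10 * hmax)
  fit <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$convergence == 0
  if (!converged) {
    # coarse grid fallback
    grid <- expand.grid(
      nugget = seq(0, gmax, length.out = 11),
      sill = seq(0, 2 * gmax, length.out = 21),
      range = exp(seq(log(hmax / 100), log(2 * hmax), length.out = 21)))
    vals <- apply(grid, 1, obj)
    best <- as.numeric(grid[which.min(vals), ])
    fit <- list(par = best, value = min(vals))
  }
  structure(list(nugget = unname(fit$par[1]), sill = unname(fit$par[2]),
                 range = unname(fit$par[3]), family = family,
                 empirical = emp, converged = converged,
                 objective = fit$value),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget = %.4g, sill = %.4g, range = %.4g%s\n",
              x$family, x$nugget, x$sill, x$range,
              if (x$converged) "" else " (grid fallback)"))
  invisible(x)
}

#' Predict model semivariance at given lags
#'
#' @param object a `variogram_model`.
#' @param lag lags at which to evaluate.
#' @param ... unused.
#' @export
predict.variogram_model <- function(object, lag, ...) {
  variogram_gamma(lag, object$nugget, object$sill, object$range,
                  object$family)
}

#' Spatially structured randomization test of transfer-function skill
#'
#' Fits a variogram to the observed gradient, then repeatedly replaces the
#' gradient by an unconditional Gaussian random field with that variogram
#' (same spatial structure, same mean and marginal variance), refits the WA
#' model and records its r². A transfer function has significant predictive
#' power when the actual r² exceeds 95% of the simulations.
#'
#' @param abundance site-by-taxon training matrix.
#' @param x observed gradient (working scale).
#' @param coords site coordinates.
#' @param n_sim number of simulations (>= 1).
#' @param family variogram family for the null fields.
#' @param cv `"apparent"` (default) scores each refit by apparent r²;
#'   `"loo"` uses jackknifed r² (slower).
#' @param coord_mode `"planar"` or `"lonlat"`.
#' @param n_bins,max_lag passed to [empirical_variogram].
#' @param seed RNG seed.
#' @param ... options passed to [wa_fit].
#' @return list of class `random_tf_result`: `r2_actual`, `r2_simulated`,
#'   `percentile` (of the actual model among simulations), `p` (with +1
#'   correction), and the fitted `variogram`.
#' @export
random_tf_test <- function(abundance, x, coords, n_sim = 999,
                           family = "exponential",
                           cv = c("apparent", "loo"),
                           coord_mode = c("planar", "lonlat"),
                           n_bins = 15, max_lag = NULL, seed = NULL, ...) {
  cv <- match.arg(cv)
  coord_mode <- match.arg(coord_mode)
  if (n_sim < 1) stop("n_sim must be >= 1")
  y <- as_abundance_matrix(abundance)
  emp <- empirical_variogram(coords, x, n_bins = n_bins, max_lag = max_lag,
                             coord_mode = coord_mode)
  vg <- fit_variogram(emp, family = family)
  if (vg$nugget + vg$sill <= 0)
    stop("variogram fit degenerate (zero total variance); test aborted")
  score <- function(xx) {
    if (cv == "apparent") {
      m <- suppressWarnings(wa_fit(y, xx, ...))
      r_squared(xx, predict(m, y)$fit)
    } else {
      suppressWarnings(wa_jackknife(y, xx, ...))$r2_jack
    }
  }
  r2_actual <- score(x)
  D <- pair_distances(coords, coord_mode)
  r2_sim <- with_seed(seed, {
    Z <- grf_draws(D, vg$nugget, vg$sill, vg$range, vg$family,
                   n_draws = n_sim)
    apply(Z + mean(x), 2, function(xs) tryCatch(score(xs),
                                                error = function(e) NA_real_))
  })
  r2_sim <- r2_sim[is.finite(r2_sim)]
  if (!length(r2_sim)) stop("all null simulations failed")
  p <- (1 + sum(r2_sim >= r2_actual)) / (length(r2_sim) + 1)
  structure(list(r2_actual = r2_actual, r2_simulated = r2_sim,
                 percentile = 100 * mean(r2_sim < r2_actual),
                 p = p, variogram = vg, cv = cv),
            class = "random_tf_result")
}

#' @export
print.random_tf_result <- function(x, ...) {
  cat(sprintf(paste0("Randomization test (%d spatially structured nulls, ",
                     "%s r2)\n  actual r2 = %.3f, percentile = %.1f, ",
                     "p = %.4g\n"),
              length(x$r2_simulated), x$cv, x$r2_actual, x$percentile, x$p))
  invisible(x)
}

#' Random / neighbourhood / environmental site-deletion curves
#'
#' For each deletion radius and each test sample during leave-one-out
#' cross-validation, deletes training sites (1) within the geographic
#' radius of the test site, (2) the same *count* of sites nearest to the
#' test site in gradient value, and (3) the same count at random; each
#' scheme's pooled predictions give one r² per radius. Under spatial
#' autocorrelation the geographic curve falls well below the random curve.
#'
#' @inheritParams random_tf_test
#' @param radii increasing deletion radii (same units as the coordinates;
#'   0 reproduces the plain jackknife in every scheme).
#' @return data.frame of class `rne_result` with columns `radius`, `scheme`
#'   (`random`/`geographic`/`environmental`), `r2`, `mean_deleted`,
#'   `n_skipped`.
#' @export
rne_test <- function(abundance, x, coords, radii = c(0, 50, 100, 200, 300),
                     coord_mode = c("planar", "lonlat"), seed = NULL, ...) {
  coord_mode <- match.arg(coord_mode)
  y <- as_abundance_matrix(abundance)
  n <- nrow(y)
  D <- pair_distances(coords, coord_mode)
  env_d <- abs(outer(x, x, "-"))
  predict_one <- function(i, drop) {
    keep <- setdiff(seq_len(n), c(i, drop))
    if (length(keep) < 5L) return(NA_real_)
    m <- tryCatch(
      suppressWarnings(wa_fit(y[keep, , drop = FALSE], x[keep], ...)),
      error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    suppressWarnings(predict(m, y[i, , drop = FALSE])$fit)
  }
  with_seed(seed, {
    rows <- list()
    for (r in radii) {
      preds <- list(random = rep(NA_real_, n),
                    geographic = rep(NA_real_, n),
                    environmental = rep(NA_real_, n))
      deleted <- integer(n)
      for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        geo_drop <- others[D[i, others] <= r]
        cnt <- length(geo_drop)
        deleted[i] <- cnt
        env_drop <- others[order(env_d[i, others])][seq_len(cnt)]
        rnd_drop <- if (cnt > 0) sample(others, cnt) else integer(0)
        preds$geographic[i] <- predict_one(i, geo_drop)
        preds$environmental[i] <- predict_one(i, env_drop)
        preds$random[i] <- predict_one(i, rnd_drop)
      }
      for (sch in names(preds)) {
        ok <- is.finite(preds[[sch]])
        rows[[length(rows) + 1L]] <- data.frame(
          radius = r, scheme = sch,
          r2 = r_squared(x[ok], preds[[sch]][ok]),
          mean_deleted = mean(deleted), n_skipped = sum(!ok))
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("rne_result", "data.frame")
    out
  })
}
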