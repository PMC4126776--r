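#' Taxa abundant enough to calibrate
#'
#' A taxon is eligible when it occurs (nonzero abundance) in strictly more
#' than `min_occurrences` samples. The conventional screens are 5 occurrences
#' for coefficient tables and 10 for the GAM permutation tests.
#'
#' @param abundance site-by-taxon matrix (any basis).
#' @param min_occurrences occurrence threshold (strict `>`).
#' @return character vector of taxon names, input order preserved.
#' @export
eligible_taxa <- function(abundance, min_occurrences = 5) {
  m <- as_abundance_matrix(abundance)
  if (ncol(m) == 0L) return(character(0))
  colnames(m)[colSums(m > 0) > min_occurrences]
}

#' Linear response of a taxon along a gradient
#'
#' Ordinary least-squares slope sign, reported only when the Pearson
#' product-moment correlation is significant at `alpha`; otherwise the sign
#' is 0.
#'
#' @param abundance_k per-site abundance of one taxon.
#' @param x gradient on the working (transformed) scale.
#' @param alpha significance level.
#' @return list with `sign` (-1, 0, +1), `r`, `p`.
#' @export
fit_linear <- function(abundance_k, x, alpha = 0.05) {
  ok <- is.finite(abundance_k) & is.finite(x)
  y <- abundance_k[ok]; x <- x[ok]
  if (length(y) < 3L) stop("need at least 3 sites with data")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(sign = 0L, r = NA_real_, p = 1))
  ct <- stats::cor.test(y, x, method = "pearson")
  r <- unname(ct$estimate)
  list(sign = if (ct$p.value < alpha) as.integer(sign(r)) else 0L,
       r = r, p = ct$p.value)
}

#' Gaussian (unimodal) response fit and its optimum
#'
#' Fits the standard unimodal response model — a quadratic in the gradient
#' on a log link (Gaussian-logit response) — and takes the optimum as the
#' argmax of the fitted curve: `-b1/(2*b2)` when the quadratic coefficient
#' is negative, otherwise the gradient boundary with the larger fitted
#' value. The optimum is clipped to the observed gradient range. The fit is
#' judged better than linear by a paired t-test on the absolute residuals of
#' the two fits.
#'
#' @inheritParams fit_linear
#' @return list with `optimum`, `better_than_linear` (logical),
#'   `p_residuals` (paired t-test p), `converged`.
#' @export
fit_gaussian <- function(abundance_k, x, alpha = 0.05) {
  ok <- is.finite(abundance_k) & is.finite(x)
  y <- abundance_k[ok]; x <- x[ok]
  if (length(y) < 5L) stop("need at least 5 sites with data")
  rng <- range(x)
  lin <- stats::lm(y ~ x)
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ x + I(x^2), family = stats::quasipoisson())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(stats::coef(fit)))) {
    # degenerate unimodal fit: fall back to the linear model, flag false
    opt <- if (unname(stats::coef(lin)[2]) >= 0) rng[2] else rng[1]
    return(list(optimum = opt, better_than_linear = FALSE,
                p_residuals = NA_real_, converged = FALSE))
  }
  b <- stats::coef(fit)
  opt <- if (is.finite(b[3]) && b[3] < 0) {
    unname(-b[2] / (2 * b[3]))
  } else {
    # convex/monotone on the log scale: argmax sits on a boundary
    mu_end <- stats::predict(fit, newdata = data.frame(x = rng))
    rng[which.max(mu_end)]
  }
  opt <- min(max(opt, rng[1]), rng[2])
  res_g <- abs(y - stats::fitted(fit))
  res_l <- abs(stats::residuals(lin))
  p_res <- if (stats::sd(res_g - res_l) == 0) 1 else
    stats::t.test(res_g, res_l, paired = TRUE)$p.value
  better <- is.finite(p_res) && p_res < alpha && mean(res_g) < mean(res_l)
  list(optimum = opt, better_than_linear = better, p_residuals = p_res,
       converged = TRUE)
}

#' Weighted-averaging optimum of a taxon
#'
#' The abundance-weighted mean of the gradient values where the taxon
#' occurs: `u = sum(y_i * x_i) / sum(y_i)`. Scale-invariant in the
#' abundances.
#'
#' @inheritParams fit_linear
#' @return the optimum in working-gradient units; `NA` when the taxon has
#'   zero total abundance.
#' @export
wa_optimum <- function(abundance_k, x) {
  ok <- is.finite(abundance_k) & is.finite(x)
  y <- abundance_k[ok]; x <- x[ok]
  tot <- sum(y)
  if (tot <= 0) return(NA_real_)
  sum(y * x) / tot
}

#' Weighted-averaging tolerance of a taxon
#'
#' Abundance-weighted standard deviation of gradient values around the
#' taxon's WA optimum.
#'
#' @inheritParams fit_linear
#' @return tolerance in working-gradient units; `NA` for zero total
#'   abundance.
#' @export
wa_tolerance <- function(abundance_k, x) {
  ok <- is.finite(abundance_k) & is.finite(x)
  y <- abundance_k[ok]; x <- x[ok]
  tot <- sum(y)
  if (tot <= 0) return(NA_real_)
  u <- sum(y * x) / tot
  sqrt(sum(y * (x - u)^2) / tot)
}

#' Rescale an optimum to a 0-10 indicator value
#'
#' Linear map of the working-scale optimum onto the observed gradient range,
#' times 10, rounded half-up to an integer — the "environmental indicator
#' value" convention.
#'
#' @param optimum optimum on the working gradient scale.
#' @param gradient_min,gradient_max observed working-scale gradient range.
#' @return integer in 0..10 (`NA` for a missing optimum).
#' @export
rescale_indicator <- function(optimum, gradient_min, gradient_max) {
  if (gradient_min >= gradient_max) stop("gradient_min must be < gradient_max")
  out <- rep(NA_integer_, length(optimum))
  ok <- is.finite(optimum)
  o <- optimum[ok]
  if (any(o < gradient_min | o > gradient_max)) {
    warning("optimum outside gradient range clipped")
    o <- pmin(pmax(o, gradient_min), gradient_max)
  }
  out[ok] <- as.integer(round_half_up(10 * (o - gradient_min) /
                                        (gradient_max - gradient_min)))
  out
}

#' Seasonal or lake specificity of a taxon on a 0-10 scale
#'
#' Per-category share of a taxon's summed abundance, scaled by 10 and
#' rounded half-up: a taxon occurring only in summer scores spring 0 /
#' summer 10.
#'
#' @param abundance_k per-sample abundance of one taxon.
#' @param labels per-sample category (season or lake), factor or character.
#' @return named integer vector over the categories.
#' @export
categorical_specificity <- function(abundance_k, labels) {
  if (length(labels) != length(abundance_k)) stop("labels length mismatch")
  if (anyNA(labels)) stop("every sample must be labeled")
  f <- factor(labels)
  tot <- sum(abundance_k)
  shares <- if (tot > 0) {
    tapply(abundance_k, f, sum, default = 0) / tot
  } else {
    stats::setNames(rep(0, nlevels(f)), levels(f))
  }
  stats::setNames(as.integer(round_half_up(10 * shares)), levels(f))
}

# One GAM deviance-explained evaluation; returns NA on smoother failure.
gam_dev_expl <- function(y, x, k = 5) {
  fit <- tryCatch(
    mgcv::gam(y ~ s(x, k = k), method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  summary(fit)$dev.expl
}

#' Permutation test of a taxon's smooth response to TP
#'
#' Fits a penalized-spline GAM of abundance on TP (modest basis, REML
#' smoothness selection) and assesses the deviance explained against
#' `n_perm` Monte Carlo permutations of TP across samples. The permutation
#' p-value uses the +1 correction, so `p >= 1/(n_perm+1)`.
#'
#' @param abundance_k per-sample (relative) abundance of one taxon.
#' @param tp TP on the working (log10) scale.
#' @param n_perm number of permutations (default 199).
#' @param k spline basis dimension.
#' @param seed RNG seed.
#' @return list with `deviance_explained`, `p`, `testable`.
#' @export
gam_tp_significance <- function(abundance_k, tp, n_perm = 199, k = 5,
                                seed = NULL) {
  ok <- is.finite(abundance_k) & is.finite(tp)
  y <- abundance_k[ok]; x <- tp[ok]
  obs <- gam_dev_expl(y, x, k)
  if (!is.finite(obs))
    return(list(deviance_explained = NA_real_, p = NA_real_,
                testable = FALSE))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) gam_dev_expl(y, sample(x), k),
           numeric(1))
  })
  perm <- perm[is.finite(perm)]
  p <- (1 + sum(perm >= obs)) / (length(perm) + 1)
  list(deviance_explained = obs, p = p, testable = TRUE)
}

#' Permutation test of TP's unique effect given a covariate
#'
#' Tests the added deviance explained by a TP smooth over a covariate-only
#' smooth model (typically alkalinity), by permuting TP while holding the
#' covariate fixed. Quantifies whether a taxon's apparent TP response
#' survives removal of a confounded gradient.
#'
#' @inheritParams gam_tp_significance
#' @param covariate the conditioning variable (working scale), e.g.
#'   alkalinity.
#' @return list with `added_deviance`, `p`, `testable`.
#' @export
gam_tp_given_cov <- function(abundance_k, tp, covariate, n_perm = 199,
                             k = 5, seed = NULL) {
  ok <- is.finite(abundance_k) & is.finite(tp) & is.finite(covariate)
  y <- abundance_k[ok]; x <- tp[ok]; z <- covariate[ok]
  added <- function(xx) {
    f0 <- tryCatch(mgcv::gam(y ~ s(z, k = k), method = "REML"),
                   error = function(e) NULL)
    f1 <- tryCatch(mgcv::gam(y ~ s(z, k = k) + s(xx, k = k), method = "REML"),
                   error = function(e) NULL)
    if (is.null(f0) || is.null(f1)) return(NA_real_)
    summary(f1)$dev.expl - summary(f0)$dev.expl
  }
  obs <- added(x)
  if (!is.finite(obs))
    return(list(added_deviance = NA_real_, p = NA_real_, testable = FALSE))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) added(sample(x)), numeric(1))
  })
  perm <- perm[is.finite(perm)]
  p <- (1 + sum(perm >= obs)) / (length(perm) + 1)
  list(added_deviance = obs, p = p, testable = TRUE)
}

#' Assemble the per-taxon coefficient checklist
#'
#' For every eligible taxon and every environmental variable, computes the
#' linear sign (Pearson, at `alpha`), the Gaussian optimum with its
#' better-than-linear flag, the WA optimum, and 0-10 indicator values for
#' both optima; plus per-taxon season and lake specificity scores when the
#' table carries those labels.
#'
#' @param abundance site-by-taxon matrix in the chosen basis.
#' @param env an [env_table]; all its variables are used unless `variables`
#'   is given.
#' @param basis one of `"density"`, `"biovolume"`, `"rel_density"`,
#'   `"rel_biovolume"`.
#' @param variables subset of environmental variables to calibrate against.
#' @param min_occurrences eligibility screen (strict `>`).
#' @param alpha significance level for the linear sign and the residual
#'   t-test.
#' @return list of class `coefficient_table`: `coefficients` (long-format
#'   data.frame: taxon, variable, lin_sign, lin_p, gaussian_optimum,
#'   better_than_linear, wa_optimum, indicator_gau, indicator_wa),
#'   `season_specificity`, `lake_specificity`, `basis`, `gradient_ranges`.
#' @export
build_coefficient_table <- function(abundance, env, basis = c(
                                      "rel_density", "density", "biovolume",
                                      "rel_biovolume"),
                                    variables = NULL, min_occurrences = 5,
                                    alpha = 0.05) {
  basis <- match.arg(basis)
  m <- as_abundance_matrix(abundance)
  x_all <- env_values(env, transformed = TRUE)
  if (is.null(variables)) variables <- colnames(x_all)
  taxa <- eligible_taxa(m, min_occurrences)
  rows <- list()
  ranges <- stats::setNames(vector("list", length(variables)), variables)
  for (v in variables) {
    x <- x_all[, v]
    rng <- range(x[is.finite(x)])
    ranges[[v]] <- rng
    for (tx in taxa) {
      y <- m[, tx]
      lin <- fit_linear(y, x, alpha)
      gau <- fit_gaussian(y, x, alpha)
      wa <- wa_optimum(y, x)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, variable = v,
        lin_sign = lin$sign, lin_p = lin$p,
        gaussian_optimum = gau$optimum,
        better_than_linear = gau$better_than_linear,
        wa_optimum = wa,
        indicator_gau = rescale_indicator(gau$optimum, rng[1], rng[2]),
        indicator_wa = rescale_indicator(wa, rng[1], rng[2]),
        stringsAsFactors = FALSE)
    }
  }
  coef_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), variable = character(0),
               lin_sign = integer(0), lin_p = numeric(0),
               gaussian_optimum = numeric(0),
               better_than_linear = logical(0), wa_optimum = numeric(0),
               indicator_gau = integer(0), indicator_wa = integer(0))
  spec_tab <- function(labels) {
    if (is.null(labels) || !length(taxa)) return(NULL)
    t(vapply(taxa, function(tx) categorical_specificity(m[, tx], labels),
             integer(nlevels(factor(labels)))))
  }
  structure(list(coefficients = coef_df,
                 season_specificity = spec_tab(env$season),
                 lake_specificity = spec_tab(env$lake),
                 basis = basis, taxa = taxa,
                 gradient_ranges = ranges),
            class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat("Coefficient table (", x$basis, "): ", length(x$taxa), " taxa x ",
      length(x$gradient_ranges), " variables\n", sep = "")
  invisible(x)
}

#' Write a coefficient table as CSV
#'
#' Writes the long-format coefficients and, when present, the season/lake
#' specificity blocks as additional columns merged by taxon.
#'
#' @param x a `coefficient_table`.
#' @param path output CSV path.
#' @export
write_coefficient_table <- function(x, path) {
  stopifnot(inherits(x, "coefficient_table"))
  df <- x$coefficients
  add_block <- function(df, block, prefix) {
    if (is.null(block)) return(df)
    b <- as.data.frame(block)
    names(b) <- paste0(prefix, "_", names(b))
    b$taxon <- rownames(block)
    merge(df, b, by = "taxon", all.x = TRUE, sort = FALSE)
  }
  df <- add_block(df, x$season_specificity, "season")
  df <- add_block(df, x$lake_specificity, "lake")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
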