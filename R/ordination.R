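#' Redundancy analysis of assemblage data
#'
#' RDA — PCA constrained to environmental predictors. The species matrix is
#' column-centred (optionally Hellinger-transformed first), each species is
#' regressed on the standardized predictors, a PCA of the fitted values
#' yields the constrained axes and a PCA of the residuals the unconstrained
#' axes. With `env = NULL` this reduces to an unconstrained PCA of the
#' species data. Axis variance fractions are relative to the total species
#' variance, so constrained + unconstrained fractions sum to 1. Site scores
#' are weighted sums of species scores (the centred species data projected
#' on the species eigenvectors), the convention that makes passive
#' projection of fossil samples exact.
#'
#' @param species site-by-taxon matrix (relative abundances by convention;
#'   centred, not standardized).
#' @param env data.frame/matrix of predictors, standardized internally;
#'   collinear predictors are dropped with a warning (deterministic order).
#' @param condition optional conditioning predictors for partial RDA:
#'   species and predictors are residualized on them first.
#' @param hellinger apply the Hellinger transformation (square root of
#'   relative abundances) before centring?
#' @param n_axes number of axes to retain in each block.
#' @return An `rda_model`: `kind`, `species_scores` and `site_scores`
#'   (constrained block, or PCA axes when unconstrained),
#'   `unconstrained_species_scores`, `unconstrained_site_scores`,
#'   `constrained_fractions`, `unconstrained_fractions`, `total_inertia`,
#'   taxon `centers` (training means retained for projection),
#'   `conditioning_variables`.
#' @export
rda_fit <- function(species, env = NULL, condition = NULL, hellinger = FALSE,
                    n_axes = 4) {
  Y <- as_abundance_matrix(species)
  if (hellinger) Y <- sqrt(to_relative(Y))
  n <- nrow(Y)
  centers <- colMeans(Y)
  Yc <- sweep(Y, 2, centers)
  total <- sum(Yc^2) / (n - 1)
  cond_names <- character(0)
  if (!is.null(condition)) {
    Z <- standardize_predictors(condition, n)
    cond_names <- colnames(Z)
    qz <- qr(cbind(1, Z))
    Yc <- qr.resid(qz, Yc)
  }
  if (is.null(env)) {
    sv <- svd(Yc)
    k <- min(n_axes, sum(sv$d > 1e-12))
    eig <- sv$d^2 / (n - 1)
    eig <- eig[eig > 1e-12 * total]
    V <- sv$v[, seq_len(k), drop = FALSE]
    rownames(V) <- colnames(Y)
    out <- list(kind = if (length(cond_names)) "partial-PCA" else "PCA",
                species_scores = V,
                site_scores = Yc %*% V,
                unconstrained_species_scores = V,
                unconstrained_site_scores = Yc %*% V,
                constrained_fractions = numeric(0),
                unconstrained_fractions = eig / total,
                eig_constrained = numeric(0), eig_unconstrained = eig,
                total_inertia = total, centers = centers,
                hellinger = hellinger, conditioning_variables = cond_names)
    class(out) <- "rda_model"
    return(out)
  }
  X <- standardize_predictors(env, n)
  if (!is.null(condition)) {
    X <- qr.resid(qz, X)
  }
  if (n <= ncol(X)) stop("need more samples than predictors")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("collinear predictor(s) dropped: ",
            paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    qx <- qr(X)
  }
  Yfit <- qr.fitted(qx, Yc)
  Yres <- Yc - Yfit
  svf <- svd(Yfit)
  svr <- svd(Yres)
  eig_c <- svf$d^2 / (n - 1)
  eig_u <- svr$d^2 / (n - 1)
  eig_c <- eig_c[eig_c > 1e-12 * total]
  eig_u <- eig_u[eig_u > 1e-12 * total]
  kc <- min(n_axes, length(eig_c))
  ku <- min(n_axes, length(eig_u))
  Vc <- svf$v[, seq_len(max(kc, 1L)), drop = FALSE]
  Vu <- svr$v[, seq_len(max(ku, 1L)), drop = FALSE]
  rownames(Vc) <- rownames(Vu) <- colnames(Y)
  out <- list(kind = if (length(cond_names)) "partial-RDA" else "RDA",
              species_scores = Vc,
              site_scores = Yc %*% Vc,
              unconstrained_species_scores = Vu,
              unconstrained_site_scores = Yc %*% Vu,
              constrained_fractions = eig_c / total,
              unconstrained_fractions = eig_u / total,
              eig_constrained = eig_c, eig_unconstrained = eig_u,
              total_inertia = total, centers = centers,
              hellinger = hellinger, conditioning_variables = cond_names,
              predictors = colnames(X))
  class(out) <- "rda_model"
  out
}

standardize_predictors <- function(env, n) {
  X <- as.matrix(as.data.frame(env))
  if (nrow(X) != n) stop("predictor rows != samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  scale(X)
}

#' @export
print.rda_model <- function(x, ...) {
  cat(x$kind, "of", nrow(x$species_scores), "taxa; total inertia",
      signif(x$total_inertia, 4), "\n")
  if (length(x$constrained_fractions))
    cat("constrained axis fractions:",
        paste(signif(utils::head(x$constrained_fractions, 4), 3),
              collapse = ", "), "\n")
  cat("unconstrained axis fractions:",
      paste(signif(utils::head(x$unconstrained_fractions, 4), 3),
            collapse = ", "), "\n")
  invisible(x)
}

# Fast path: constrained variance fraction of a single-predictor RDA.
# x is centred; fraction = sum_j (x . Y_j)^2 / (x'x) / ((n-1) * total).
single_variable_fraction <- function(Yc, x, total) {
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) return(NA_real_)
  sum(as.numeric(crossprod(Yc, xc))^2) / ss / (nrow(Yc) - 1) / total
}

#' Marginal permutation tests of environmental variables
#'
#' For each variable, the constrained variance fraction of a
#' single-variable RDA is compared with `n_perm` permutations of that
#' variable's rows (marginal tests; the significant subset conventionally
#' feeds the final RDA).
#'
#' @inheritParams rda_fit
#' @param variables which predictors to test (default all).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return data.frame with `variable`, `constrained_fraction`, `p` (with +1
#'   correction).
#' @export
permutation_significance <- function(species, env, variables = NULL,
                                     n_perm = 999, hellinger = FALSE,
                                     seed = NULL) {
  Y <- as_abundance_matrix(species)
  if (hellinger) Y <- sqrt(to_relative(Y))
  Yc <- sweep(Y, 2, colMeans(Y))
  total <- sum(Yc^2) / (nrow(Y) - 1)
  env <- as.data.frame(env)
  if (is.null(variables)) variables <- colnames(env)
  with_seed(seed, {
    out <- lapply(variables, function(v) {
      x <- env[[v]]
      obs <- single_variable_fraction(Yc, x, total)
      perm <- vapply(seq_len(n_perm), function(i)
        single_variable_fraction(Yc, sample(x), total), numeric(1))
      data.frame(variable = v, constrained_fraction = obs,
                 p = (1 + sum(perm >= obs)) / (n_perm + 1))
    })
    do.call(rbind, out)
  })
}

#' Total and unique variance explained by a focal variable
#'
#' Variance partitioning by (partial) RDA: the total contribution of the
#' focal variable is the constrained fraction of an RDA on it alone; the
#' unique contribution is the constrained fraction of a partial RDA on the
#' focal variable after residualizing species and predictor on the
#' conditioning variables — both expressed as fractions of the *original*
#' total species variance.
#'
#' @inheritParams rda_fit
#' @param focal name of the focal predictor in `env`.
#' @param conditioners names of the conditioning predictors (must not
#'   include `focal`).
#' @return list with `total_fraction`, `unique_fraction`, and `note` when
#'   the conditioners span the focal variable exactly.
#' @export
variance_partition <- function(species, env, focal, conditioners,
                               hellinger = FALSE) {
  env <- as.data.frame(env)
  if (focal %in% conditioners) stop("focal must not be a conditioner")
  Y <- as_abundance_matrix(species)
  if (hellinger) Y <- sqrt(to_relative(Y))
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  total_inertia <- sum(Yc^2) / (n - 1)
  xf <- env[[focal]]
  total_fraction <- single_variable_fraction(Yc, xf, total_inertia)
  Z <- standardize_predictors(env[, conditioners, drop = FALSE], n)
  qz <- qr(cbind(1, Z))
  x_res <- qr.resid(qz, matrix(xf - mean(xf), ncol = 1))
  note <- NULL
  if (sum(x_res^2) < 1e-10 * sum((xf - mean(xf))^2)) {
    note <- "conditioners span the focal variable; unique fraction is 0"
    unique_fraction <- 0
  } else {
    Y_res <- qr.resid(qz, Yc)
    unique_fraction <- single_variable_fraction(Y_res, as.numeric(x_res),
                                                total_inertia)
  }
  list(total_fraction = total_fraction, unique_fraction = unique_fraction,
       note = note)
}

#' Project fossil assemblages passively onto a training ordination
#'
#' Fossil taxa are intersected with the training taxa, abundances
#' renormalized over the intersection, centred with the *training* taxon
#' means, and multiplied by the training species scores (weighted-sum
#' projection). Scores come back in core order (by date) so the downcore
#' trajectory can be traced through the training ordination space.
#'
#' @param model an `rda_model` fitted to training assemblages.
#' @param fossil a [core_strat] or an interval-by-taxon relative abundance
#'   matrix.
#' @param axes which constrained axes to return.
#' @return matrix of fossil site scores (intervals x axes), with attribute
#'   `"coverage"` (pre-renormalization share of fossil abundance on
#'   training taxa).
#' @export
passive_project <- function(model, fossil, axes = 1:2) {
  stopifnot(inherits(model, "rda_model"))
  m <- if (inherits(fossil, "core_strat")) fossil$assemblage else
    as_abundance_matrix(fossil)
  common <- intersect(colnames(m), rownames(model$species_scores))
  if (!length(common)) stop("no taxa shared between fossil samples and model")
  coverage <- rowSums(m[, common, drop = FALSE]) /
    pmax(rowSums(m), .Machine$double.eps)
  ym <- to_relative(m[, common, drop = FALSE])
  if (model$hellinger) ym <- sqrt(ym)
  axes <- axes[axes <= ncol(model$species_scores)]
  V <- model$species_scores[common, axes, drop = FALSE]
  yc <- sweep(ym, 2, model$centers[common])
  scores <- yc %*% V
  attr(scores, "coverage") <- coverage
  scores
}
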