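#' Construct a water-quality table with a transform registry
#'
#' Bundles site-by-variable measurements (original units) with the
#' per-variable transformation used to remove skew, optional site
#' coordinates, and optional season/lake labels. The transform registry
#' travels with the table so calibration models and data can never silently
#' disagree about the scale a variable is analysed on.
#'
#' @param values data.frame of numeric measurements, one row per site.
#'   Row names (or a `site_id` column) identify sites.
#' @param coords optional data.frame with columns `x`,`y` (planar km) or
#'   `lon`,`lat`.
#' @param transforms named character vector over variables, each one of
#'   `"none"`, `"log"` (base 10) or `"sqrt"`; variables not named default to
#'   `"none"`.
#' @param season,lake optional per-site labels.
#' @param coord_mode `"planar"` or `"lonlat"`.
#' @param log_offsets named numeric vector of offsets added before a log
#'   transform; a variable with zeros and no configured offset gets half its
#'   smallest positive value (reported with a message).
#' @return A list of class `env_table`.
#' @export
env_table <- function(values, coords = NULL, transforms = NULL,
                      season = NULL, lake = NULL,
                      coord_mode = c("planar", "lonlat"),
                      log_offsets = NULL) {
  coord_mode <- match.arg(coord_mode)
  values <- as.data.frame(values)
  if ("site_id" %in% names(values)) {
    rownames(values) <- values$site_id
    values$site_id <- NULL
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("site ids missing or duplicated")
  if (!all(vapply(values, is.numeric, logical(1))))
    stop("all environmental variables must be numeric")
  tr <- stats::setNames(rep("none", ncol(values)), names(values))
  if (!is.null(transforms)) {
    bad <- setdiff(names(transforms), names(values))
    if (length(bad)) stop("transforms name unknown variables: ",
                          paste(bad, collapse = ", "))
    tr[names(transforms)] <- transforms
  }
  if (!all(tr %in% c("none", "log", "sqrt")))
    stop("transforms must be none, log or sqrt")
  offs <- stats::setNames(rep(0, ncol(values)), names(values))
  if (!is.null(log_offsets)) offs[names(log_offsets)] <- log_offsets
  for (v in names(values)[tr == "log"]) {
    x <- values[[v]]
    if (offs[v] == 0 && any(x <= 0, na.rm = TRUE)) {
      pos <- x[x > 0 & is.finite(x)]
      if (!length(pos))
        stop("variable '", v, "' has no positive values; cannot log-transform")
      offs[v] <- min(pos) / 2
      message("variable '", v, "' contains nonpositive values; ",
              "using log offset ", signif(offs[v], 4))
    }
  }
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    if (coord_mode == "planar" && !all(c("x", "y") %in% names(coords)))
      names(coords)[1:2] <- c("x", "y")
    if (coord_mode == "lonlat" && !all(c("lon", "lat") %in% names(coords)))
      names(coords)[1:2] <- c("lon", "lat")
    if (nrow(coords) != nrow(values)) stop("coords rows != sites")
    rownames(coords) <- rownames(values)
  }
  structure(list(values = values, transforms = tr, log_offsets = offs,
                 coords = coords, season = season, lake = lake,
                 coord_mode = coord_mode),
            class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat("Environment table:", nrow(x$values), "sites x", ncol(x$values),
      "variables\n")
  tr <- x$transforms[x$transforms != "none"]
  if (length(tr))
    cat("transforms:", paste(names(tr), tr, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$coords)) cat("coordinates:", x$coord_mode, "\n")
  invisible(x)
}

#' Extract site-by-variable values from an environment table
#'
#' @param env an [env_table].
#' @param transformed if `TRUE`, apply each variable's registered transform
#'   (the "working scale" used by every model in the package).
#' @return numeric matrix, sites in rows.
#' @export
env_values <- function(env, transformed = FALSE) {
  stopifnot(inherits(env, "env_table"))
  m <- as.matrix(env$values)
  if (!transformed) return(m)
  for (v in colnames(m)) {
    m[, v] <- transform_variable(m[, v], env$transforms[[v]],
                                 offset = env$log_offsets[[v]], name = v)
  }
  m
}

#' Transform a variable to its working scale
#'
#' `"log"` is base 10 throughout the package; `"sqrt"` is the square root;
#' `"none"` is the identity. The inverse is exact on the transform's range
#' (see [inverse_transform_variable]).
#'
#' @param values numeric vector in original units.
#' @param kind `"none"`, `"log"` or `"sqrt"`.
#' @param offset added before a log transform (for variables with zero
#'   minima).
#' @param name variable name used in error messages.
#' @return transformed numeric vector.
#' @examples
#' transform_variable(100, "log")  # 2
#' transform_variable(81, "sqrt")  # 9
#' @export
transform_variable <- function(values, kind = c("none", "log", "sqrt"),
                               offset = 0, name = "variable") {
  kind <- match.arg(kind)
  switch(kind,
    none = values,
    log = {
      shifted <- values + offset
      bad <- which(shifted <= 0)
      if (length(bad))
        stop("log transform of '", name, "': nonpositive value at site(s) ",
             paste(utils::head(bad, 5), collapse = ", "),
             " (configure a log offset)")
      log10(shifted)
    },
    sqrt = {
      if (any(values < 0, na.rm = TRUE))
        stop("sqrt transform of '", name, "': negative values present")
      sqrt(values)
    }
  )
}

#' Invert a working-scale transform back to original units
#'
#' @inheritParams transform_variable
#' @param values numeric vector on the working scale.
#' @export
inverse_transform_variable <- function(values, kind = c("none", "log", "sqrt"),
                                       offset = 0) {
  kind <- match.arg(kind)
  switch(kind,
    none = values,
    log = 10^values - offset,
    sqrt = values^2
  )
}

# Molar masses (g/mol) used for nutrient ratio variables.
.molar_mass <- c(N = 14.0067, P = 30.973762, Si = 28.0855)

#' Append molar nutrient-ratio variables (N:P, N:Si, P:Si)
#'
#' Converts mass concentrations to molar concentrations using the molar
#' masses of N, P and Si and appends the three ratios as new variables with
#' their conventional skew-removing transforms (sqrt for N:P, log for N:Si
#' and P:Si). Default units follow common monitoring practice: nitrate +
#' nitrite and silica in mg/L, phosphorus in ug/L.
#'
#' @param env an [env_table] containing the nitrogen, phosphorus and silica
#'   variables.
#' @param n_variable,p_variable,si_variable column names of the inputs.
#' @param units named character vector giving each input's units, `"mg/L"`
#'   or `"ug/L"`.
#' @return the [env_table] with `NtoP`, `NtoSi`, `PtoSi` appended; a zero
#'   denominator yields a missing ratio with a warning, never a failure.
#' @export
derive_ratios <- function(env, n_variable = "NOx", p_variable = "TP",
                          si_variable = "Silica",
                          units = c(NOx = "mg/L", TP = "ug/L",
                                    Silica = "mg/L")) {
  stopifnot(inherits(env, "env_table"))
  need <- c(n_variable, p_variable, si_variable)
  miss <- setdiff(need, names(env$values))
  if (length(miss)) stop("missing input variables: ",
                         paste(miss, collapse = ", "))
  to_umol <- function(x, unit, element) {
    ug <- switch(unit, "mg/L" = x * 1000, "ug/L" = x,
                 stop("unknown unit: ", unit))
    ug / .molar_mass[[element]]
  }
  u <- stats::setNames(units[c(1, 2, 3)], NULL)
  n_mol <- to_umol(env$values[[n_variable]], u[1], "N")
  p_mol <- to_umol(env$values[[p_variable]], u[2], "P")
  si_mol <- to_umol(env$values[[si_variable]], u[3], "Si")
  safe_ratio <- function(num, den, nm) {
    zero <- !is.na(den) & den == 0
    if (any(zero))
      warning(sum(zero), " zero denominator(s) in ", nm,
              "; set to missing")
    out <- num / den
    out[zero] <- NA_real_
    out
  }
  env$values$NtoP <- safe_ratio(n_mol, p_mol, "NtoP")
  env$values$NtoSi <- safe_ratio(n_mol, si_mol, "NtoSi")
  env$values$PtoSi <- safe_ratio(p_mol, si_mol, "PtoSi")
  env$transforms <- c(env$transforms,
                      c(NtoP = "sqrt", NtoSi = "log", PtoSi = "log"))
  env$log_offsets <- c(env$log_offsets, c(NtoP = 0, NtoSi = 0, PtoSi = 0))
  for (v in c("NtoSi", "PtoSi")) {
    x <- env$values[[v]]
    if (any(x <= 0, na.rm = TRUE)) {
      pos <- x[x > 0 & is.finite(x)]
      env$log_offsets[[v]] <- if (length(pos)) min(pos) / 2 else 1e-6
      message("ratio '", v, "' contains nonpositive values; log offset ",
              signif(env$log_offsets[[v]], 4))
    }
  }
  env
}

#' Principal components of the environmental data
#'
#' PCA of the correlation matrix of transformed variables (all variables
#' scaled to zero mean and unit variance). The first `n_axes` site scores
#' can be appended to the table as new variables `PC1`, `PC2`, ... for use
#' in species-response screening.
#'
#' @param env an [env_table].
#' @param n_axes number of axes exposed as new variables.
#' @param augment if `TRUE`, return the env_table with score variables
#'   appended (in `$env`).
#' @return list of class `pca_summary`: `loadings` (variable x axis),
#'   `scores` (site x axis), `eigenvalue_fractions`, `n_used` (sites after
#'   listwise deletion), and optionally `env`.
#' @export
pca_environment <- function(env, n_axes = 2, augment = FALSE) {
  x <- env_values(env, transformed = TRUE)
  keep <- stats::complete.cases(x)
  if (sum(!keep) > 0)
    message("pca_environment: ", sum(!keep), " incomplete sites dropped")
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 complete sites")
  if (ncol(x) < 2L) stop("need at least 2 variables")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  fractions <- fit$sdev^2 / sum(fit$sdev^2)
  out <- list(loadings = fit$rotation, scores = fit$x,
              eigenvalue_fractions = fractions,
              center = fit$center, scale = fit$scale,
              n_used = nrow(x))
  class(out) <- "pca_summary"
  if (augment) {
    scores <- matrix(NA_real_, nrow(env$values), n_axes)
    scores[keep, ] <- fit$x[, seq_len(n_axes), drop = FALSE]
    colnames(scores) <- paste0("PC", seq_len(n_axes))
    env$values <- cbind(env$values, as.data.frame(scores))
    env$transforms <- c(env$transforms,
                        stats::setNames(rep("none", n_axes),
                                        colnames(scores)))
    env$log_offsets <- c(env$log_offsets,
                         stats::setNames(rep(0, n_axes), colnames(scores)))
    out$env <- env
  }
  out
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("PCA of", length(x$eigenvalue_fractions), "variables,", x$n_used,
      "sites\n")
  cat("axis variance fractions:",
      paste(signif(utils::head(x$eigenvalue_fractions, 4), 3),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Pairwise Pearson correlation screen with Bonferroni flags
#'
#' Pearson product-moment correlations between all transformed variables,
#' with significance at `alpha` Bonferroni-corrected over the number of
#' unordered variable pairs.
#'
#' @param env an [env_table].
#' @param alpha family-wise significance level.
#' @return list of class `cor_screen`: `r`, raw `p`, logical `significant`
#'   (after correction), pairwise `n`, and `n_tests`.
#' @export
correlation_screen <- function(env, alpha = 0.05) {
  x <- env_values(env, transformed = TRUE)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 variables")
  r <- pval <- nmat <- matrix(NA_real_, p, p, dimnames = list(colnames(x),
                                                              colnames(x)))
  diag(r) <- 1; diag(pval) <- 0; diag(nmat) <- colSums(!is.na(x))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- stats::complete.cases(x[, c(i, j)])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L)
        stop("fewer than 3 complete pairs for ", colnames(x)[i], " vs ",
             colnames(x)[j])
      ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  n_tests <- p * (p - 1) / 2
  structure(list(r = r, p = pval, significant = pval < alpha / n_tests,
                 n = nmat, n_tests = n_tests, alpha = alpha),
            class = "cor_screen")
}

#' @export
print.cor_screen <- function(x, ...) {
  cat("Correlation screen over", nrow(x$r), "variables (",
      x$n_tests, "pairs, Bonferroni at alpha =", x$alpha, ")\n")
  print(round(x$r, 2))
  invisible(x)
}
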