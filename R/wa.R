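#' Fit a weighted-averaging transfer function
#'
#' Weighted-averaging (WA) regression of a gradient (canonically log10-TP)
#' on relative taxon abundances: taxon optima are abundance-weighted means
#' of the gradient, tolerances abundance-weighted standard deviations;
#' initial sample estimates are (optionally tolerance-downweighted)
#' abundance-weighted means of the optima; and inverse deshrinking regresses
#' the observed gradient on the initial estimates to undo the range
#' shrinkage of averaging twice. The default configuration is WA with
#' tolerance downweighting and inverse deshrinking on untransformed relative
#' abundances.
#'
#' @param abundance site-by-taxon matrix; rows are renormalized to relative
#'   abundances (the calibration basis).
#' @param x gradient on the working scale (e.g. log10-TP, µg/L).
#' @param tolerance_dw use tolerance downweighting (weights `y/t^2`)?
#' @param deshrink `"inverse"` (OLS of observed on initial estimates) or
#'   `"none"`.
#' @param species_transform optional transformation of the abundances before
#'   calibration: `"none"` (default), `"sqrt"`, or `"log1p"`.
#' @param tolerance_floor taxa with tolerances below this floor have them
#'   raised to it (guards division by near-zero for single-occurrence
#'   taxa); default `sd(x)/10`.
#' @return A `wa_model`: taxon `optima` and `tolerances`, deshrinking
#'   coefficients `b0`,`b1`, the options, the gradient transform label, and
#'   a training fingerprint (taxa, sample count, gradient range).
#' @examples
#' y <- rbind(a = c(10, 0), b = c(5, 5), c = c(0, 10))
#' colnames(y) <- c("t1", "t2")
#' m <- wa_fit(y, c(1, 2, 3), tolerance_dw = FALSE)
#' @export
wa_fit <- function(abundance, x, tolerance_dw = TRUE,
                   deshrink = c("inverse", "none"),
                   species_transform = c("none", "sqrt", "log1p"),
                   tolerance_floor = NULL) {
  deshrink <- match.arg(deshrink)
  species_transform <- match.arg(species_transform)
  y <- as_abundance_matrix(abundance)
  if (length(x) != nrow(y)) stop("gradient length != samples")
  if (any(!is.finite(x))) stop("gradient must be finite")
  y <- apply_species_transform(to_relative(y), species_transform)
  tot <- colSums(y)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " taxa with zero total abundance dropped")
    y <- y[, tot > 0, drop = FALSE]
    tot <- colSums(y)
  }
  if (ncol(y) == 0L) stop("no taxa left to calibrate")
  u <- as.numeric(crossprod(y, x)) / tot
  t2 <- as.numeric(crossprod(y, x^2)) / tot - u^2
  tol <- sqrt(pmax(t2, 0))
  if (is.null(tolerance_floor)) tolerance_floor <- stats::sd(x) / 10
  tol_raw <- tol
  tol <- pmax(tol, tolerance_floor)
  names(u) <- names(tol) <- names(tol_raw) <- colnames(y)
  x0 <- wa_initial(y, u, tol, tolerance_dw)
  if (deshrink == "inverse") {
    if (stats::sd(x0) == 0) stop("degenerate initial estimates; cannot deshrink")
    co <- stats::coef(stats::lm(x ~ x0))
    b0 <- unname(co[1]); b1 <- unname(co[2])
  } else {
    b0 <- 0; b1 <- 1
  }
  structure(list(optima = u, tolerances = tol, tolerances_raw = tol_raw,
                 b0 = b0, b1 = b1,
                 options = list(tolerance_dw = tolerance_dw,
                                deshrink = deshrink,
                                species_transform = species_transform,
                                tolerance_floor = tolerance_floor),
                 gradient_transform = "log10",
                 fingerprint = list(taxa = colnames(y), n_samples = nrow(y),
                                    gradient_range = range(x)),
                 fitted_initial = x0,
                 fitted = b0 + b1 * x0,
                 observed = x),
            class = "wa_model")
}

apply_species_transform <- function(y, kind) {
  switch(kind, none = y, sqrt = sqrt(y), log1p = log1p(y))
}

# Initial WA estimates: abundance-weighted average of optima, with optional
# tolerance downweighting. Rows with zero weight return NA.
wa_initial <- function(y, u, tol, tolerance_dw) {
  w <- if (tolerance_dw) sweep(y, 2, tol^2, "/") else y
  num <- as.numeric(w %*% u)
  den <- rowSums(w)
  ifelse(den > 0, num / den, NA_real_)
}

#' @export
print.wa_model <- function(x, ...) {
  cat("WA transfer function (", x$gradient_transform, " gradient): ",
      length(x$optima), " taxa, ", x$fingerprint$n_samples, " samples\n",
      sep = "")
  cat("  tolerance downweighting:", x$options$tolerance_dw,
      "| deshrinking:", x$options$deshrink, "\n")
  cat("  deshrink b0 =", signif(x$b0, 4), ", b1 =", signif(x$b1, 4), "\n")
  invisible(x)
}

#' Infer the gradient for new assemblages from a WA model
#'
#' Renormalizes each assemblage over the taxa the model was trained on,
#' takes the (tolerance-downweighted, if the model was fitted that way)
#' weighted average of the taxon optima and applies the deshrinking
#' regression. The fraction of each sample's abundance belonging to modeled
#' taxa is reported as `coverage` so fossil applications can flag poor
#' taxonomic overlap.
#'
#' @param object a `wa_model`.
#' @param newdata site-by-taxon abundance matrix.
#' @param ... unused.
#' @return data.frame with `fit` (deshrunk inference, working-gradient
#'   units), `raw` (pre-deshrinking estimate) and `coverage`; samples
#'   sharing no taxa with the model get `NA` and are flagged in the
#'   `no_analog` column.
#' @export
predict.wa_model <- function(object, newdata, ...) {
  y <- as_abundance_matrix(newdata)
  y <- apply_species_transform(to_relative(y),
                               object$options$species_transform)
  taxa <- object$fingerprint$taxa
  common <- intersect(colnames(y), taxa)
  coverage <- if (length(common)) {
    rowSums(y[, common, drop = FALSE]) / pmax(rowSums(y), .Machine$double.eps)
  } else rep(0, nrow(y))
  if (!length(common)) {
    return(data.frame(fit = NA_real_, raw = NA_real_, coverage = coverage,
                      no_analog = TRUE, row.names = rownames(y)))
  }
  ys <- y[, common, drop = FALSE]
  raw <- wa_initial(ys, object$optima[common], object$tolerances[common],
                    object$options$tolerance_dw)
  fit <- object$b0 + object$b1 * raw
  data.frame(fit = fit, raw = raw, coverage = coverage,
             no_analog = !is.finite(raw), row.names = rownames(y))
}

#' Leave-one-out jackknife validation of a WA model
#'
#' Refits the full pipeline (optima, tolerances, deshrinking) with each
#' sample held out in turn and predicts the held-out sample, giving
#' cross-validated r² and RMSEP that correct the optimism of apparent
#' statistics.
#'
#' @inheritParams wa_fit
#' @param ... options passed to [wa_fit].
#' @return A `crossval_report`: `r2_apparent`, `rmse_apparent`, `r2_jack`,
#'   `rmsep_jack` (working-gradient units), per-sample `predictions`
#'   (observed, apparent, jackknife), and the count of samples that could
#'   not be predicted when held out.
#' @export
wa_jackknife <- function(abundance, x, ...) {
  y <- as_abundance_matrix(abundance)
  n <- nrow(y)
  if (n < 10L) stop("jackknifing needs at least 10 samples")
  full <- wa_fit(y, x, ...)
  apparent <- predict(full, y)$fit
  jack <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      suppressWarnings(wa_fit(y[-i, , drop = FALSE], x[-i], ...)),
      error = function(e) NULL)
    if (is.null(fit_i)) next
    jack[i] <- suppressWarnings(
      predict(fit_i, y[i, , drop = FALSE])$fit)
  }
  excluded <- sum(!is.finite(jack))
  if (excluded)
    message("wa_jackknife: ", excluded,
            " sample(s) unpredictable when held out; excluded")
  ok <- is.finite(jack)
  structure(list(r2_apparent = r_squared(x, apparent),
                 rmse_apparent = rmse(x, apparent),
                 r2_jack = r_squared(x[ok], jack[ok]),
                 rmsep_jack = rmse(x[ok], jack[ok]),
                 predictions = data.frame(observed = x, apparent = apparent,
                                          jackknife = jack,
                                          row.names = rownames(y)),
                 n_excluded = excluded, model = full),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("WA cross-validation (leave-one-out jackknife)\n")
  cat(sprintf("  apparent:  r2 = %.3f, RMSE  = %.3f\n", x$r2_apparent,
              x$rmse_apparent))
  cat(sprintf("  jackknife: r2 = %.3f, RMSEP = %.3f\n", x$r2_jack,
              x$rmsep_jack))
  if (x$n_excluded) cat("  excluded samples:", x$n_excluded, "\n")
  invisible(x)
}

#' Modern analog technique inference
#'
#' Infers the gradient for each test assemblage as the unweighted mean of
#' the observed gradient values of its `k` most compositionally similar
#' training assemblages. The default dissimilarity is the squared chord
#' distance on relative abundances. Ties at the k-th distance are all
#' included (and noted in `k_used`).
#'
#' @param training site-by-taxon training abundances.
#' @param training_x observed gradient for the training samples.
#' @param test test assemblages (columns matched by name; absent taxa count
#'   as zero).
#' @param k number of analogs.
#' @param metric `"sq_chord"` (default) or `"euclidean"`.
#' @return data.frame with `fit`, `k_used`, `min_distance`; the full
#'   test-by-training distance matrix is attached as attribute
#'   `"distances"`.
#' @export
mat_predict <- function(training, training_x, test, k = 5,
                        metric = c("sq_chord", "euclidean")) {
  metric <- match.arg(metric)
  ytr <- to_relative(as_abundance_matrix(training))
  yte <- to_relative(as_abundance_matrix(test))
  if (k > nrow(ytr)) stop("k exceeds the number of training samples")
  taxa <- union(colnames(ytr), colnames(yte))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(taxa), dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }
  ytr <- pad(ytr); yte <- pad(yte)
  D <- squared_chord_distances(yte, ytr, metric)
  res <- t(vapply(seq_len(nrow(yte)), function(i) {
    d <- D[i, ]
    dk <- sort(d, partial = k)[k]
    sel <- which(d <= dk + 1e-12)
    c(fit = mean(training_x[sel]), k_used = length(sel),
      min_distance = min(d))
  }, numeric(3)))
  out <- as.data.frame(res)
  rownames(out) <- rownames(yte)
  attr(out, "distances") <- D
  out
}

# All test-vs-training dissimilarities; squared chord distance is
# sum((sqrt(p) - sqrt(q))^2), the discipline default for assemblage data.
squared_chord_distances <- function(a, b, metric = "sq_chord") {
  if (metric == "sq_chord") {
    a <- sqrt(a); b <- sqrt(b)
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2 <- pmax(d2, 0)
  if (metric == "euclidean") sqrt(d2) else d2
}

#' Serialize a WA model to a plain-text coefficient file
#'
#' Header lines (`# key: value`) carry the gradient transform, options,
#' deshrinking coefficients and training fingerprint; the body is a CSV of
#' taxon, optimum, tolerance.
#'
#' @param model a `wa_model`.
#' @param path output path.
#' @export
write_wa_model <- function(model, path) {
  stopifnot(inherits(model, "wa_model"))
  hdr <- c(
    "# phytocal wa_model v1",
    paste0("# gradient_transform: ", model$gradient_transform),
    paste0("# tolerance_dw: ", model$options$tolerance_dw),
    paste0("# deshrink: ", model$options$deshrink),
    paste0("# species_transform: ", model$options$species_transform),
    paste0("# tolerance_floor: ", format(model$options$tolerance_floor,
                                         digits = 17)),
    paste0("# b0: ", format(model$b0, digits = 17)),
    paste0("# b1: ", format(model$b1, digits = 17)),
    paste0("# n_samples: ", model$fingerprint$n_samples),
    paste0("# gradient_range: ",
           paste(format(model$fingerprint$gradient_range, digits = 17),
                 collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(taxon = names(model$optima),
                              optimum = model$optima,
                              tolerance = model$tolerances),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a serialized WA model
#'
#' @param path file written by [write_wa_model].
#' @return a `wa_model` (without training fitted values).
#' @export
read_wa_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("missing header field: ", key)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  u <- stats::setNames(body$optimum, body$taxon)
  tol <- stats::setNames(body$tolerance, body$taxon)
  structure(list(optima = u, tolerances = tol, tolerances_raw = tol,
                 b0 = as.numeric(get("b0")), b1 = as.numeric(get("b1")),
                 options = list(
                   tolerance_dw = as.logical(get("tolerance_dw")),
                   deshrink = get("deshrink"),
                   species_transform = get("species_transform"),
                   tolerance_floor = as.numeric(get("tolerance_floor"))),
                 gradient_transform = get("gradient_transform"),
                 fingerprint = list(
                   taxa = body$taxon,
                   n_samples = as.integer(get("n_samples")),
                   gradient_range = as.numeric(strsplit(get("gradient_range"),
                                                        ",")[[1]]))),
            class = "wa_model")
}
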