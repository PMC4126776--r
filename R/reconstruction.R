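#' Reconstruct the gradient downcore from fossil assemblages
#'
#' Applies a WA transfer function to every core interval, reporting the
#' diatom-inferred value on the working (log10) scale and back-transformed
#' to original units (µg/L for TP), with an error band of ± the jackknife
#' RMSEP drawn on the working scale and back-transformed (hence asymmetric
#' in original units). Intervals whose modelled-taxon coverage falls below
#' `coverage_floor` are flagged, never dropped; zero-coverage intervals get
#' a missing inference.
#'
#' @param model a `wa_model`.
#' @param core a [core_strat].
#' @param crossval a `crossval_report` from [wa_jackknife] (its
#'   `rmsep_jack` feeds the band), or a single numeric RMSEP.
#' @param coverage_floor coverage below which an interval is flagged.
#' @return data.frame of class `reconstruction`: `year`, `depth`,
#'   `ditp` (working scale), `ditp_back` (original units), `band_lo`,
#'   `band_hi` (original units), `coverage`, `flagged`.
#' @export
reconstruct_core <- function(model, core, crossval = NULL,
                             coverage_floor = 0.5) {
  stopifnot(inherits(model, "wa_model"), inherits(core, "core_strat"))
  rmsep <- if (inherits(crossval, "crossval_report")) crossval$rmsep_jack
           else if (is.numeric(crossval)) crossval
           else NA_real_
  pr <- predict(model, core$assemblage)
  back <- function(v) inverse_transform_variable(v, "log")
  out <- data.frame(year = core$year, depth = core$depth,
                    ditp = pr$fit, ditp_back = back(pr$fit),
                    band_lo = back(pr$fit - rmsep),
                    band_hi = back(pr$fit + rmsep),
                    coverage = pr$coverage,
                    flagged = pr$coverage < coverage_floor | pr$no_analog,
                    row.names = rownames(core$assemblage))
  if (any(pr$no_analog))
    warning(sum(pr$no_analog), " interval(s) share no taxa with the model")
  class(out) <- c("reconstruction", "data.frame")
  attr(out, "rmsep") <- rmsep
  out
}

#' Ratio of constrained to maximum explainable first-axis variance
#'
#' `lambda_R` is the variance fraction captured by the first axis of an RDA
#' of the core assemblages constrained to the reconstruction alone;
#' `lambda_P` the fraction captured by the first axis of an unconstrained
#' PCA of the same assemblages. Their ratio expresses how much of the
#' maximum explainable assemblage variance the reconstructed variable
#' accounts for; it cannot exceed 1 (a constrained axis cannot beat the
#' leading eigenvector).
#'
#' @param core_species interval-by-taxon relative abundances (or a
#'   [core_strat]).
#' @param ditp reconstructed values per interval (working scale).
#' @return list with `lambda_r`, `lambda_p`, `ratio`.
#' @export
lambda_ratio <- function(core_species, ditp) {
  Y <- if (inherits(core_species, "core_strat")) core_species$assemblage
       else as_abundance_matrix(core_species)
  ok <- is.finite(ditp)
  if (sum(ok) < 3L) stop("need at least 3 intervals with a reconstruction")
  Y <- Y[ok, , drop = FALSE]; ditp <- ditp[ok]
  if (stats::sd(ditp) == 0) stop("constant reconstruction; ratio undefined")
  keep <- colSums(Y) > 0
  Y <- Y[, keep, drop = FALSE]
  rda <- rda_fit(Y, data.frame(ditp = ditp))
  pca <- rda_fit(Y)
  lr <- if (length(rda$constrained_fractions)) rda$constrained_fractions[1]
        else 0
  lp <- pca$unconstrained_fractions[1]
  list(lambda_r = unname(lr), lambda_p = unname(lp),
       ratio = unname(lr / lp))
}

#' Correlation between the reconstruction and the core's main gradient
#'
#' Pearson correlation between the downcore reconstruction and the
#' interval scores on axis 1 of an unconstrained PCA of the fossil
#' assemblages. The raw signed correlation is returned (a PCA axis sign is
#' arbitrary) together with its magnitude.
#'
#' @inheritParams lambda_ratio
#' @return list with `r` (signed), `abs_r`, `n`.
#' @export
ditp_pca_correlation <- function(core_species, ditp) {
  Y <- if (inherits(core_species, "core_strat")) core_species$assemblage
       else as_abundance_matrix(core_species)
  ok <- is.finite(ditp)
  if (sum(ok) < 3L) stop("need at least 3 intervals with a reconstruction")
  Y <- Y[ok, , drop = FALSE]; d <- ditp[ok]
  if (stats::sd(d) == 0) stop("constant reconstruction; correlation undefined")
  pca <- rda_fit(Y)
  s1 <- pca$unconstrained_site_scores[, 1]
  r <- stats::cor(d, s1)
  list(r = r, abs_r = abs(r), n = length(d))
}
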