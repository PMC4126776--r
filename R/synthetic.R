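#' Define a pool of taxa with known unimodal responses
#'
#' A species pool records, for each taxon, the "true" Gaussian response along
#' the calibration gradient: the optimum (gradient position of maximal
#' expected abundance), the tolerance (niche breadth, the standard deviation
#' of the Gaussian response) and the expected abundance at the optimum.
#' Downstream calibration code never sees these truths; they exist so that
#' optimum recovery, transfer-function skill and reconstruction fidelity can
#' be measured against a known answer.
#'
#' @param true_optimum numeric vector of optima on the (transformed) gradient
#'   scale, e.g. log10-TP units.
#' @param true_tolerance strictly positive niche breadths, same units.
#' @param max_abundance expected abundance at the optimum (recycled).
#' @param group taxon group label, e.g. `"diatom"` or `"soft-alga"` (recycled).
#' @param taxon_id taxon labels; defaults to `taxon01`, `taxon02`, ...
#' @return A `data.frame` of class `species_pool`.
#' @examples
#' pool <- species_pool(true_optimum = c(0.5, 1.2), true_tolerance = 0.3)
#' @export
species_pool <- function(true_optimum, true_tolerance, max_abundance = 1,
                         group = "diatom", taxon_id = NULL) {
  n <- length(true_optimum)
  if (n < 2L) stop("a species pool needs at least 2 taxa")
  if (any(!is.finite(true_optimum))) stop("optima must be finite")
  true_tolerance <- rep_len(true_tolerance, n)
  if (any(!is.finite(true_tolerance)) || any(true_tolerance <= 0))
    stop("tolerances must be strictly positive")
  max_abundance <- rep_len(max_abundance, n)
  if (any(max_abundance < 0)) stop("max_abundance must be >= 0")
  if (is.null(taxon_id))
    taxon_id <- sprintf("taxon%02d", seq_len(n))
  if (anyDuplicated(taxon_id)) stop("duplicated taxon_id")
  out <- data.frame(taxon_id = as.character(taxon_id),
                    true_optimum = as.numeric(true_optimum),
                    true_tolerance = as.numeric(true_tolerance),
                    max_abundance = as.numeric(max_abundance),
                    group = rep_len(as.character(group), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("species_pool", "data.frame")
  out
}

#' Draw a random species pool along a gradient
#'
#' Convenience generator: optima uniform over `optimum_range`, tolerances
#' uniform over `tolerance_range`, maximal abundances log-uniform over
#' `max_abundance_range`.
#'
#' @param n_taxa number of taxa.
#' @param optimum_range,tolerance_range,max_abundance_range length-2 ranges.
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @return A [species_pool].
#' @export
random_species_pool <- function(n_taxa, optimum_range = c(0, 2),
                                tolerance_range = c(0.2, 0.6),
                                max_abundance_range = c(0.2, 5),
                                seed = NULL) {
  with_seed(seed, {
    species_pool(
      true_optimum = stats::runif(n_taxa, optimum_range[1], optimum_range[2]),
      true_tolerance = stats::runif(n_taxa, tolerance_range[1], tolerance_range[2]),
      max_abundance = exp(stats::runif(n_taxa, log(max_abundance_range[1]),
                                       log(max_abundance_range[2])))
    )
  })
}

#' Specify the variogram of a simulated environmental field
#'
#' @param mean field mean in variable units.
#' @param nugget,sill nonnegative variance components; `nugget + sill` is the
#'   marginal variance of the field.
#' @param range correlation range parameter (> 0), in distance units (km).
#' @param family covariance family: exponential (default), spherical or
#'   gaussian.
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(mean = 0, nugget = 0, sill = 1, range = 50,
                       family = c("exponential", "spherical", "gaussian")) {
  family <- match.arg(family)
  if (nugget < 0 || sill < 0) stop("nugget and sill must be >= 0")
  if (range <= 0) stop("range must be > 0")
  structure(list(mean = mean, nugget = nugget, sill = sill, range = range,
                 family = family), class = "field_spec")
}

# Correlation function of a variogram family (correlogram, no nugget).
cov_family_rho <- function(h, range, family) {
  switch(family,
    exponential = exp(-h / range),
    gaussian = exp(-(h / range)^2),
    spherical = ifelse(h < range,
                       1 - 1.5 * (h / range) + 0.5 * (h / range)^3, 0),
    stop("unknown covariance family: ", family)
  )
}

# Draw `n_draws` mean-zero Gaussian random fields over sites with pairwise
# distance matrix D, covariance sill*rho(D) + nugget*I, by Cholesky
# factorization of the full covariance (exact at desk scale).
grf_draws <- function(D, nugget, sill, range, family, n_draws = 1L) {
  n <- nrow(D)
  total <- nugget + sill
  if (total <= 0) return(matrix(0, n, n_draws))
  C <- sill * cov_family_rho(D, range, family)
  diag(C) <- total
  # small jitter keeps the factorization stable for smooth families
  L <- chol(C + diag(1e-10 * total, n))
  crossprod(L, matrix(stats::rnorm(n * n_draws), n, n_draws))
}

#' Simulate spatially autocorrelated environmental fields
#'
#' Generates one Gaussian random field per variable with the requested
#' marginal variogram, then induces cross-variable correlation by linearly
#' mixing the independent standardized fields through the symmetric square
#' root of `correlation`. Marginal variances are preserved exactly; marginal
#' variogram shapes are preserved approximately when variables have different
#' ranges (exactly when they share one).
#'
#' @param coords data.frame or matrix of site positions with columns
#'   `x`,`y` (planar, km) or `lon`,`lat`.
#' @param specs named list of [field_spec], one per variable.
#' @param correlation optional variable-by-variable correlation matrix
#'   (symmetric positive semi-definite); identity if omitted.
#' @param coord_mode `"planar"` (Euclidean km) or `"lonlat"` (great-circle km).
#' @param seed RNG seed.
#' @return An [env_table]; simulated values are already on the working
#'   (transformed) scale, so every transform is registered as `"none"`.
#' @examples
#' xy <- data.frame(x = runif(20, 0, 100), y = runif(20, 0, 100))
#' env <- simulate_environment(xy, list(TP = field_spec(mean = 1, sill = 0.2)),
#'                             seed = 1)
#' @export
simulate_environment <- function(coords, specs, correlation = NULL,
                                 coord_mode = c("planar", "lonlat"),
                                 seed = NULL) {
  coord_mode <- match.arg(coord_mode)
  coords <- as.data.frame(coords)
  if (coord_mode == "planar" && !all(c("x", "y") %in% names(coords)))
    names(coords)[1:2] <- c("x", "y")
  if (anyDuplicated(coords[, 1:2])) stop("site coordinates must be distinct")
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    stop("specs must be a named list of field_spec objects")
  p <- length(specs)
  n <- nrow(coords)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (nrow(correlation) != p || ncol(correlation) != p)
      stop("correlation must be ", p, "x", p)
    if (max(abs(correlation - t(correlation))) > 1e-8)
      stop("correlation matrix is not symmetric")
    ev <- eigen(correlation, symmetric = TRUE)
    if (min(ev$values) < -1e-8)
      stop("correlation matrix is not positive semi-definite ",
           "(smallest eigenvalue ", signif(min(ev$values), 3), ")")
    mix <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  } else {
    mix <- diag(p)
  }
  D <- pair_distances(coords[, 1:2], coord_mode)
  vals <- with_seed(seed, {
    # independent standardized fields, one per variable, each with its own
    # variogram shape
    Z <- matrix(0, n, p)
    for (j in seq_len(p)) {
      s <- specs[[j]]
      if (!inherits(s, "field_spec")) stop("specs[[", j, "]] is not a field_spec")
      total <- s$nugget + s$sill
      if (total > 0)
        Z[, j] <- grf_draws(D, s$nugget, s$sill, s$range, s$family) / sqrt(total)
    }
    X <- Z %*% mix
    for (j in seq_len(p)) {
      s <- specs[[j]]
      total <- s$nugget + s$sill
      X[, j] <- if (total > 0) s$mean + sqrt(total) * X[, j] else rep(s$mean, n)
    }
    X
  })
  colnames(vals) <- names(specs)
  values <- as.data.frame(vals)
  env_table(values,
            coords = coords[, 1:2],
            transforms = stats::setNames(rep("none", p), names(specs)),
            coord_mode = coord_mode)
}

#' Simulate training-set assemblages from Gaussian taxon responses
#'
#' Expected abundance of taxon k at site i is
#' `max_abundance_k * exp(-(x_i - u_k)^2 / (2 t_k^2))` where `x` is the
#' gradient variable on its working scale. Under `"multinomial"` noise the
#' expected abundances are converted to proportions and `count_total` valves
#' are drawn per sample (the conventional diatom count); `"poisson"` and
#' `"negative_binomial"` draw absolute abundances around the expectation.
#'
#' @param pool a [species_pool].
#' @param env an [env_table] containing `gradient_variable`.
#' @param gradient_variable name of the gradient column (working scale).
#' @param count_total valves counted per sample (multinomial total), >= 1.
#' @param noise `"multinomial"` (default), `"poisson"`, or
#'   `"negative_binomial"`.
#' @param nb_size dispersion parameter k for negative-binomial noise.
#' @param seed RNG seed.
#' @return Site-by-taxon count matrix with attribute `basis = "density"`;
#'   taxa absent from every sample are dropped with a warning.
#' @export
simulate_assemblages <- function(pool, env, gradient_variable = "TP",
                                 count_total = 400,
                                 noise = c("multinomial", "poisson",
                                           "negative_binomial"),
                                 nb_size = 5, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(pool, "species_pool"))
  x <- env_values(env, transformed = TRUE)[, gradient_variable]
  if (is.null(x)) stop("gradient variable '", gradient_variable, "' not in env")
  if (count_total < 1) stop("count_total must be >= 1")
  n <- length(x)
  m <- nrow(pool)
  expected <- outer(x, pool$true_optimum, "-")
  expected <- exp(-expected^2 / (2 * rep(pool$true_tolerance^2, each = n)))
  expected <- expected * rep(pool$max_abundance, each = n)
  counts <- with_seed(seed, {
    switch(noise,
      multinomial = {
        t(vapply(seq_len(n), function(i) {
          p <- expected[i, ]
          if (sum(p) <= 0) return(rep(0, m))
          as.numeric(stats::rmultinom(1, size = count_total, prob = p / sum(p)))
        }, numeric(m)))
      },
      poisson = matrix(stats::rpois(n * m, lambda = expected), n, m),
      negative_binomial = matrix(
        stats::rnbinom(n * m, size = nb_size, mu = expected), n, m)
    )
  })
  dimnames(counts) <- list(rownames(env_values(env)), pool$taxon_id)
  absent <- colSums(counts) == 0
  if (any(absent)) {
    warning(sum(absent), " taxa absent from every sample were dropped: ",
            paste(pool$taxon_id[absent], collapse = ", "))
    counts <- counts[, !absent, drop = FALSE]
  }
  attr(counts, "basis") <- "density"
  counts
}

#' Describe a downcore scenario with a known TP trajectory
#'
#' @param dates strictly monotone vector of interval years.
#' @param tp_trajectory true gradient value (working scale, e.g. log10-TP)
#'   per interval.
#' @param count_total valves counted per interval.
#' @param depths optional interval depths (cm); defaults to 1..n.
#' @return A list of class `core_scenario`.
#' @export
core_scenario <- function(dates, tp_trajectory, count_total = 400,
                          depths = NULL) {
  if (length(dates) < 1L) stop("scenario needs at least one interval")
  if (length(dates) != length(tp_trajectory))
    stop("dates and tp_trajectory lengths differ")
  d <- diff(dates)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("dates must be strictly monotone")
  if (any(!is.finite(tp_trajectory))) stop("tp_trajectory must be finite")
  if (is.null(depths)) depths <- seq_along(dates)
  structure(list(dates = dates, tp_trajectory = tp_trajectory,
                 count_total = count_total, depths = depths),
            class = "core_scenario")
}

#' Simulate a sediment-core stratigraphy from the shared species pool
#'
#' Each interval's assemblage is a multinomial draw from the same Gaussian
#' response model as the training simulation, evaluated at that interval's
#' true TP, so fossil samples have analogs in any training set built from the
#' same pool. Emulates an enrichment-excursion core when `tp_trajectory`
#' ramps up and back down.
#'
#' @param pool the [species_pool] shared with the training simulation.
#' @param scenario a [core_scenario].
#' @param seed RNG seed.
#' @return A `core_strat` object: list with `counts`, relative-abundance
#'   matrix `assemblage` (rows sum to 1), `year`, `depth`, and the true
#'   trajectory in `tp_true`.
#' @export
simulate_core <- function(pool, scenario, seed = NULL) {
  stopifnot(inherits(pool, "species_pool"), inherits(scenario, "core_scenario"))
  x <- scenario$tp_trajectory
  n <- length(x)
  if (n == 0L) stop("empty trajectory")
  m <- nrow(pool)
  expected <- outer(x, pool$true_optimum, "-")
  expected <- exp(-expected^2 / (2 * rep(pool$true_tolerance^2, each = n)))
  expected <- expected * rep(pool$max_abundance, each = n)
  counts <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      p <- expected[i, ]
      as.numeric(stats::rmultinom(1, size = scenario$count_total,
                                  prob = p / sum(p)))
    }, numeric(m)))
  })
  dimnames(counts) <- list(sprintf("int%02d", seq_len(n)), pool$taxon_id)
  core_strat(assemblage = counts / rowSums(counts),
             year = scenario$dates, depth = scenario$depths,
             tp_true = x, counts = counts)
}

#' Construct a core stratigraphy object
#'
#' @param assemblage interval-by-taxon relative abundance matrix (rows sum
#'   to 1).
#' @param year chronology (years, monotone with depth).
#' @param depth interval depths (cm).
#' @param tp_true optional known trajectory (synthetic cores only).
#' @param counts optional raw count matrix.
#' @return A list of class `core_strat`.
#' @export
core_strat <- function(assemblage, year, depth = seq_along(year),
                       tp_true = NULL, counts = NULL) {
  assemblage <- as_abundance_matrix(assemblage)
  if (nrow(assemblage) != length(year)) stop("year length != intervals")
  rs <- rowSums(assemblage)
  if (any(abs(rs - 1) > 1e-6))
    stop("assemblage rows must sum to 1 (relative abundances)")
  if (length(year) > 1L) {
    dy <- diff(year[order(depth)])
    if (!(all(dy > 0) || all(dy < 0)))
      stop("dates must be monotone with depth")
  }
  structure(list(assemblage = assemblage, year = year, depth = depth,
                 tp_true = tp_true, counts = counts),
            class = "core_strat")
}

#' @export
print.core_strat <- function(x, ...) {
  cat("Core stratigraphy:", nrow(x$assemblage), "intervals,",
      ncol(x$assemblage), "taxa; years", min(x$year), "-", max(x$year), "\n")
  invisible(x)
}

#' Standard synthetic calibration benchmark
#'
#' The package's reference study conditions for desk-scale validation: 500
#' sites scattered over a 1000 x 500 km domain, a spatially autocorrelated
#' log10-TP field (exponential variogram, range 100 km, sill 0.25, nugget
#' 0.02, mean 0.8 — about 6 ug/L, spanning roughly two orders of magnitude
#' of TP across sites), 100 diatom taxa with Gaussian responses whose
#' optima span the sampled gradient, and multinomial counts of 400 valves
#' per sample.
#'
#' @param n_sites,n_taxa,count_total study dimensions.
#' @param seed RNG seed driving coordinates, field, pool and counts.
#' @param tp_spec optional [field_spec] overriding the TP field.
#' @return list with `coords`, `env` ([env_table]), `pool`
#'   ([species_pool]), `abundance` (count matrix), and `x` (the true
#'   log10-TP per site).
#' @export
simulate_benchmark <- function(n_sites = 500, n_taxa = 100,
                               count_total = 400, seed = 1,
                               tp_spec = NULL) {
  if (is.null(tp_spec))
    tp_spec <- field_spec(mean = 0.8, nugget = 0.02, sill = 0.25,
                          range = 100, family = "exponential")
  coords <- with_seed(seed, data.frame(x = stats::runif(n_sites, 0, 1000),
                                       y = stats::runif(n_sites, 0, 500)))
  env <- simulate_environment(coords, list(TP = tp_spec), seed = seed + 1)
  pool <- random_species_pool(n_taxa,
                              optimum_range = c(-0.4, 2.0),
                              tolerance_range = c(0.15, 0.5),
                              seed = seed + 2)
  abundance <- simulate_assemblages(pool, env, "TP",
                                    count_total = count_total,
                                    seed = seed + 3)
  list(coords = coords, env = env, pool = pool, abundance = abundance,
       x = env_values(env)[, "TP"])
}

#' A temporary-enrichment core scenario
#'
#' Emulates a Lake Superior-like stratigraphy: a low, stable baseline TP
#' with a smooth mid-20th-century enrichment excursion that ramps up and
#' back down. Values are log10-TP.
#'
#' @param n_intervals number of core intervals (default 26).
#' @param years chronology (default evenly spaced 1707-2010).
#' @param baseline baseline log10-TP (default 0.55, about 3.5 ug/L).
#' @param excursion peak enrichment above baseline in log10 units.
#' @param peak_year,width centre and half-width (years) of the excursion.
#' @param count_total valves per interval.
#' @return a [core_scenario].
#' @export
enrichment_scenario <- function(n_intervals = 26,
                                years = seq(1707, 2010,
                                            length.out = n_intervals),
                                baseline = 0.55, excursion = 0.45,
                                peak_year = 1950, width = 30,
                                count_total = 400) {
  traj <- baseline + excursion * exp(-((years - peak_year) / width)^2)
  core_scenario(dates = years, tp_trajectory = traj,
                count_total = count_total)
}

#' Simulate a five-basin training set with basin-scale trophic structure
#'
#' Emulates a large-lakes monitoring design: five basins whose sites
#' cluster around well-separated centres, with basin mean log10-TP spread
#' from oligotrophic to eutrophic and a short-range spatial TP field within
#' basins. Geography therefore predicts TP — the situation in which
#' neighbourhood-deletion diagnostics must show a drop. With
#' `structured = FALSE` the TP values are randomly reassigned across sites
#' (same marginal distribution, no spatial structure), the negative
#' control.
#'
#' @param n_per_basin sites per basin.
#' @param basin_tp basin mean log10-TP values (oligotrophic to eutrophic).
#' @param basin_sd within-basin site scatter (km) around the basin centre.
#' @param n_taxa taxa in the shared pool.
#' @param count_total valves per sample.
#' @param structured keep the spatial arrangement of TP?
#' @param seed RNG seed.
#' @return list with `coords`, `x` (log10-TP), `abundance`, `pool`,
#'   `basin` (factor), `env` ([env_table] carrying the lake labels).
#' @export
simulate_basin_training <- function(n_per_basin = 30,
                                    basin_tp = c(0.35, 0.65, 0.95, 1.25,
                                                 1.55),
                                    basin_sd = 40, n_taxa = 40,
                                    count_total = 400, structured = TRUE,
                                    seed = 1) {
  centers <- data.frame(x = c(100, 350, 550, 750, 950),
                        y = c(100, 350, 120, 380, 150))
  n_basin <- length(basin_tp)
  basin <- rep(seq_len(n_basin), each = n_per_basin)
  coords <- with_seed(seed, data.frame(
    x = centers$x[basin] + stats::rnorm(length(basin), 0, basin_sd),
    y = centers$y[basin] + stats::rnorm(length(basin), 0, basin_sd)))
  envf <- simulate_environment(coords, list(TP = field_spec(
    mean = 0, nugget = 0.01, sill = 0.04, range = 80)), seed = seed + 1)
  x <- env_values(envf)[, "TP"] + basin_tp[basin]
  if (!structured) x <- with_seed(seed + 2, sample(x))
  pool <- random_species_pool(n_taxa,
                              optimum_range = range(basin_tp) + c(-0.25, 0.25),
                              tolerance_range = c(0.15, 0.5),
                              seed = seed + 3)
  env <- env_table(data.frame(TP = x), coords = coords,
                   lake = paste0("basin", basin))
  abundance <- suppressWarnings(
    simulate_assemblages(pool, env, "TP", count_total = count_total,
                         seed = seed + 4))
  list(coords = coords, x = x, abundance = abundance, pool = pool,
       basin = factor(basin), env = env)
}
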