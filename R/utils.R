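#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points funnel through this so a single seed argument
# makes a whole pipeline bit-reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Round half away from zero (so 0.5 -> 1), the convention used for the
# integer 0-10 indicator values. base::round() rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

# Pairwise distances between rows of a 2-column coordinate matrix.
# mode "planar": Euclidean in the coordinate units (km by convention);
# mode "lonlat": great-circle (haversine) distances in km.
pair_distances <- function(coords, mode = c("planar", "lonlat")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  if (mode == "planar") return(as.matrix(stats::dist(coords)))
  haversine_matrix(coords[, 1L], coords[, 2L])
}

haversine_matrix <- function(lon, lat, radius_km = 6371.0088) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(phi)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

# Squared Pearson correlation, NA-safe.
r_squared <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(obs[ok], pred[ok])^2
}

rmse <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  sqrt(mean((obs[ok] - pred[ok])^2))
}

as_abundance_matrix <- function(abundance) {
  m <- as.matrix(abundance)
  if (is.null(rownames(m)) && nrow(m) > 0)
    rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m)) && ncol(m) > 0)
    colnames(m) <- paste0("t", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("abundance matrix contains missing values")
  if (any(m < 0)) stop("abundance matrix contains negative values")
  m
}

# Row-normalize an abundance matrix to relative abundances; all-zero rows
# are left at zero (flagged by callers that care).
to_relative <- function(m) {
  rs <- rowSums(m)
  out <- m / ifelse(rs > 0, rs, 1)
  out
}
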