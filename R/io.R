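#' Read a site-by-taxon abundance matrix from CSV
#'
#' Expects a rectangular CSV whose first column holds sample ids; optional
#' `season` and `lake` metadata columns are split off, every remaining
#' column is a taxon. Relative bases are verified to row-sum to 1 (within
#' 1e-6) or renormalized with a warning when `renormalize = TRUE`.
#'
#' @param path CSV path.
#' @param basis `"density"`, `"biovolume"`, `"rel_density"` or
#'   `"rel_biovolume"`.
#' @param renormalize repair off-unit row sums for relative bases?
#' @return numeric matrix with attributes `basis`, `season`, `lake`.
#' @export
read_abundance <- function(path, basis = c("density", "biovolume",
                                           "rel_density", "rel_biovolume"),
                           renormalize = TRUE) {
  basis <- match.arg(basis)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance CSV needs an id column plus taxa")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  season <- if ("season" %in% names(df)) df$season else NULL
  lake <- if ("lake" %in% names(df)) df$lake else NULL
  df <- df[, setdiff(names(df), c("season", "lake")), drop = FALSE]
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) stop("non-numeric or missing abundance values")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance at sample '", rownames(m)[neg[1, 1]],
         "', taxon '", colnames(m)[neg[1, 2]], "'")
  if (startsWith(basis, "rel")) {
    rs <- rowSums(m)
    off <- abs(rs - 1) > 1e-6
    if (any(off)) {
      if (!renormalize)
        stop(sum(off), " row(s) of a relative basis do not sum to 1")
      warning(sum(off), " row(s) renormalized to sum to 1")
      m <- to_relative(m)
    }
  }
  attr(m, "basis") <- basis
  attr(m, "season") <- season
  attr(m, "lake") <- lake
  m
}

#' Write an abundance matrix as CSV
#'
#' @param abundance matrix (with optional `season`/`lake` attributes).
#' @param path output path.
#' @export
write_abundance <- function(abundance, path) {
  m <- as_abundance_matrix(abundance)
  df <- data.frame(sample_id = rownames(m), check.names = FALSE)
  if (!is.null(attr(abundance, "season"))) df$season <- attr(abundance, "season")
  if (!is.null(attr(abundance, "lake"))) df$lake <- attr(abundance, "lake")
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

transforms_path_for <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_transforms.csv")
}

#' Write an environment table (values + transform registry)
#'
#' The measurements, coordinates and labels go to `path`; the per-variable
#' transform registry is serialized alongside (default
#' `<path>_transforms.csv`) so tables and models cannot silently disagree
#' about working scales.
#'
#' @param env an [env_table].
#' @param path CSV path for the values.
#' @param transforms_path CSV path for the registry.
#' @export
write_env_table <- function(env, path,
                            transforms_path = transforms_path_for(path)) {
  stopifnot(inherits(env, "env_table"))
  df <- data.frame(site_id = rownames(env$values), check.names = FALSE)
  if (!is.null(env$coords)) df <- cbind(df, env$coords)
  if (!is.null(env$season)) df$season <- env$season
  if (!is.null(env$lake)) df$lake <- env$lake
  df <- cbind(df, env$values)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(variable = names(env$transforms),
                              transform = unname(env$transforms),
                              log_offset = unname(env$log_offsets)),
                   transforms_path, row.names = FALSE)
  invisible(path)
}

#' Read an environment table written by [write_env_table]
#'
#' @param path CSV of measurements.
#' @param transforms_path registry CSV; every variable defaults to no
#'   transform when the file is absent.
#' @param coord_mode `"planar"` or `"lonlat"`.
#' @return an [env_table].
#' @export
read_env_table <- function(path, transforms_path = transforms_path_for(path),
                           coord_mode = c("planar", "lonlat")) {
  coord_mode <- match.arg(coord_mode)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- as.character(df$site_id)
  df$site_id <- NULL
  coord_cols <- if (coord_mode == "planar") c("x", "y") else c("lon", "lat")
  coords <- if (all(coord_cols %in% names(df))) df[, coord_cols] else NULL
  season <- if ("season" %in% names(df)) df$season else NULL
  lake <- if ("lake" %in% names(df)) df$lake else NULL
  drop <- c(coord_cols, "season", "lake")
  vals <- df[, setdiff(names(df), drop), drop = FALSE]
  transforms <- NULL; offsets <- NULL
  if (file.exists(transforms_path)) {
    reg <- utils::read.csv(transforms_path, stringsAsFactors = FALSE)
    transforms <- stats::setNames(reg$transform, reg$variable)
    offsets <- stats::setNames(reg$log_offset, reg$variable)
  }
  env_table(vals, coords = coords, transforms = transforms, season = season,
            lake = lake, coord_mode = coord_mode, log_offsets = offsets)
}

#' Read a core stratigraphy from CSV
#'
#' Expects a `year` column (chronology is an input, not computed), an
#' optional `depth` column, and taxon relative abundances in the remaining
#' columns.
#'
#' @param path CSV path.
#' @param renormalize repair off-unit row sums with a warning?
#' @return a [core_strat].
#' @export
read_core <- function(path, renormalize = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"year" %in% names(df)) stop("core CSV needs a 'year' column")
  year <- df$year
  depth <- if ("depth" %in% names(df)) df$depth else seq_along(year)
  m <- as.matrix(df[, setdiff(names(df), c("year", "depth")), drop = FALSE])
  storage.mode(m) <- "double"
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6)) {
    if (!renormalize) stop("core rows do not sum to 1")
    warning("core rows renormalized to sum to 1")
    m <- to_relative(m)
  }
  rownames(m) <- sprintf("int%02d", seq_len(nrow(m)))
  core_strat(m, year = year, depth = depth)
}

#' Write a core stratigraphy (or reconstruction) as CSV
#'
#' @param core a [core_strat].
#' @param path output path.
#' @export
write_core <- function(core, path) {
  stopifnot(inherits(core, "core_strat"))
  df <- cbind(data.frame(year = core$year, depth = core$depth),
              as.data.frame(core$assemblage, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
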