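#' Construct a gridded study landscape
#'
#' A landscape is the planar spatial domain of the diffusion model: a regular
#' grid of square cells with a water mask, a reflecting boundary, and the
#' covariate rasters that drive motility and density dependence.  Grid
#' convention: matrices indexed `[row, col]`, cell centres at
#' `((col-0.5)h, (row-0.5)h)` metres, all distances in metres.
#'
#' The covariates expected by [motility_field()] and
#' [carrying_capacity_field()] are: `depth_ind` (1 where depth < 40 m),
#' `dist_shore` (m), `slope` (dimensionless gradient of the sea floor),
#' `shore_complex` (count of shoreline cells within 1 km), `town_dist`
#' (cumulative swimmable distance to settlements, m), and the management
#' indicators `glba_ind` and `fish_ind` (protected bay, fisheries closures).
#'
#' @param water logical matrix; `TRUE` marks modelled water cells.  Cells
#'   outside the nearshore system (open ocean beyond the reflecting boundary)
#'   are `FALSE`, like land.
#' @param cell_size cell edge length in metres.
#' @param covariates named list of numeric matrices matching `dim(water)`.
#' @param towns optional data frame with columns `row`, `col` (and optionally
#'   `name`) giving settlement locations.
#' @param standardization optional named list of `c(mean, sd)` pairs recorded
#'   by [standardize_covariates()].
#' @return An object of class `eco_landscape`.
#' @seealso [standardize_covariates()], [generate_landscape()]
#' @export
landscape <- function(water, cell_size, covariates = list(), towns = NULL,
                      standardization = list()) {
  stopifnot_matrix(water)
  if (!is.logical(water)) stop("'water' must be a logical matrix")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("'cell_size' must be positive")
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    stopifnot_matrix(x, nm)
    if (!all(dim(x) == dim(water)))
      stop(sprintf("covariate '%s' does not match the water mask dimensions", nm))
    if (any(!is.finite(x[water])))
      stop(sprintf("covariate '%s' is not finite on all water cells", nm))
  }
  ls <- structure(list(
    water = water,
    cell_size = cell_size,
    n_rows = nrow(water), n_cols = ncol(water),
    boundary = water & (adjacent4_to(!water) | edge_mask(water)),
    covariates = covariates,
    towns = towns,
    standardization = standardization,
    area_per_cell = cell_size^2
  ), class = "eco_landscape")
  ls
}

# cells on the raster edge (where zero-flux also applies)
edge_mask <- function(water) {
  out <- matrix(FALSE, nrow(water), ncol(water))
  out[c(1L, nrow(water)), ] <- TRUE
  out[, c(1L, ncol(water))] <- TRUE
  out
}

#' @method print eco_landscape
#' @export
print.eco_landscape <- function(x, ...) {
  cat(sprintf("<eco_landscape> %d x %d cells of %g m (%d water, %d boundary)\n",
              x$n_rows, x$n_cols, x$cell_size, sum(x$water), sum(x$boundary)))
  cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Reintroduction epicenters
#'
#' Epicenters are the release sites seeding the Gaussian-kernel initial
#' intensity surface.  Each has an abundance scale `theta` (expected
#' individuals contributed) and an isotropic dispersal scale `kappa` (metres).
#'
#' @param row,col integer grid coordinates of each epicenter (water cells).
#' @param theta positive abundance scales.
#' @param kappa positive kernel scales in metres.
#' @param label optional site labels.
#' @param landscape optional [landscape()]; if supplied, epicenters are
#'   checked to lie on water.
#' @return A data frame of class `eco_epicenters`.
#' @export
epicenters <- function(row, col, theta, kappa, label = NULL, landscape = NULL) {
  n <- length(row)
  if (length(col) != n || length(theta) != n || length(kappa) != n)
    stop("epicenter fields must have equal length")
  if (any(theta <= 0)) stop("'theta' must be positive")
  if (any(kappa <= 0)) stop("'kappa' must be positive")
  if (is.null(label)) label <- paste0("site", seq_len(n))
  if (!is.null(landscape)) {
    on_water <- landscape$water[cbind(row, col)]
    if (!all(on_water))
      stop("epicenters must lie on water cells: ",
           paste(label[!on_water], collapse = ", "))
  }
  structure(data.frame(label = label, row = row, col = col,
                       theta = theta, kappa = kappa),
            class = c("eco_epicenters", "data.frame"))
}

#' Shoreline complexity raster
#'
#' For every cell, counts the shoreline cells whose centre lies within
#' `radius` metres (Euclidean, centre-to-centre).  A shoreline cell is a
#' water cell with at least one land cell among its 4-neighbours; the raster
#' edge is not treated as land.  Complex, convoluted shorelines therefore
#' score high and straight coasts low.
#'
#' @param water logical water mask.
#' @param radius neighbourhood radius in metres (default 1000 m).
#' @param cell_size cell edge length in metres.
#' @return Integer-valued matrix of shoreline counts.
#' @export
shoreline_complexity <- function(water, radius = 1000, cell_size) {
  stopifnot_matrix(water)
  if (radius < cell_size)
    stop("'radius' smaller than one cell width: neighbourhood is empty")
  land <- !water
  shoreline <- water & adjacent4_to(land)
  r_cells <- radius / cell_size
  half <- floor(r_cells)
  nr <- nrow(water); nc <- ncol(water)
  out <- matrix(0, nr, nc)
  S <- shoreline * 1
  for (dr in -half:half) for (dc in -half:half) {
    if (sqrt(dr^2 + dc^2) > r_cells) next
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
    out[rok, cok] <- out[rok, cok] + S[rs[rok], cs[cok]]
  }
  out
}

#' Cumulative swimmable distance to settlements
#'
#' For each water cell, the sum over towns of the shortest path length
#' through water (8-connected grid, diagonal steps weighted by sqrt(2) times
#' the cell size).  Towns on land are snapped to their nearest water cell.
#' Water cells unreachable from a town contribute that town's maximum finite
#' in-domain distance, so downstream standardization stays finite; a message
#' is emitted when this happens.
#'
#' @param water logical water mask.
#' @param towns data frame with columns `row`, `col`.
#' @param cell_size cell edge length in metres.
#' @return Matrix of cumulative distances in metres (`NA` on land).
#' @export
cumulative_town_distance <- function(water, towns, cell_size) {
  stopifnot_matrix(water)
  if (is.null(towns) || nrow(towns) == 0L) stop("no towns supplied")
  if (!any(water)) stop("water mask is empty")
  wg <- water_graph(water, cell_size, diagonal = TRUE)
  rc <- id_to_rowcol(wg$ids, nrow(water))
  # snap each town to the nearest water cell
  src <- vapply(seq_len(nrow(towns)), function(i) {
    d2 <- (rc[, 1] - towns$row[i])^2 + (rc[, 2] - towns$col[i])^2
    which.min(d2)
  }, integer(1))
  D <- igraph::distances(wg$graph, v = src, weights = igraph::E(wg$graph)$weight)
  if (any(!is.finite(D))) {
    for (i in seq_len(nrow(D))) {
      bad <- !is.finite(D[i, ])
      if (any(bad)) D[i, bad] <- max(D[i, !bad])
    }
    message("some water cells unreachable from a town; assigned the maximum finite in-domain distance")
  }
  out <- matrix(NA_real_, nrow(water), ncol(water))
  out[wg$ids] <- colSums(D)
  out
}

is_indicator_covariate <- function(x, water) {
  v <- x[water]
  all(v %in% c(0, 1))
}

#' Centre and scale covariates over water cells
#'
#' Non-indicator covariates are replaced by `(x - mean)/sd`, with mean and sd
#' computed over water cells only; binary indicator covariates are left
#' untouched.  The `(mean, sd)` pairs are recorded (and composed across
#' repeated calls) in the landscape's `standardization` field so the same
#' scaling can be replayed exactly on new inputs and inverted by
#' [destandardize_covariates()].
#'
#' @param ls an [landscape()] object.
#' @return The landscape with standardized covariates.
#' @export
standardize_covariates <- function(ls) {
  stopifnot(inherits(ls, "eco_landscape"))
  w <- ls$water
  if (sum(w) < 2L) stop("need at least two water cells to standardize")
  for (nm in names(ls$covariates)) {
    x <- ls$covariates[[nm]]
    if (is_indicator_covariate(x, w)) next
    m <- mean(x[w]); s <- sd(x[w])
    if (!is.finite(s) || s == 0)
      stop(sprintf("covariate '%s' has zero variance over water cells", nm))
    x[w] <- (x[w] - m) / s
    ls$covariates[[nm]] <- x
    prev <- ls$standardization[[nm]]
    if (is.null(prev)) {
      ls$standardization[[nm]] <- c(mean = m, sd = s)
    } else {
      # compose: raw -> prev -> now, so destandardization recovers raw input
      ls$standardization[[nm]] <- c(mean = unname(prev["mean"] + m * prev["sd"]),
                                    sd = unname(prev["sd"] * s))
    }
  }
  ls
}

#' Invert covariate standardization
#'
#' @param ls a landscape whose covariates were standardized by
#'   [standardize_covariates()].
#' @return The landscape with covariates on their original scale.
#' @export
destandardize_covariates <- function(ls) {
  stopifnot(inherits(ls, "eco_landscape"))
  w <- ls$water
  for (nm in names(ls$standardization)) {
    ms <- ls$standardization[[nm]]
    x <- ls$covariates[[nm]]
    x[w] <- x[w] * ms["sd"] + ms["mean"]
    ls$covariates[[nm]] <- x
  }
  ls$standardization <- list()
  ls
}

# covariate design matrices over water cells, in the model's fixed order
motility_design <- function(ls) {
  w <- ls$water
  need <- c("depth_ind", "dist_shore", "slope", "shore_complex",
            "town_dist", "glba_ind", "fish_ind")
  miss <- setdiff(need, names(ls$covariates))
  if (length(miss))
    stop("landscape lacks covariates: ", paste(miss, collapse = ", "))
  cv <- lapply(ls$covariates[need], function(x) x[w])
  cbind(intercept = 1, depth = cv$depth_ind, dist = cv$dist_shore,
        slope_x_depth = cv$slope * cv$depth_ind, shore = cv$shore_complex,
        town = cv$town_dist, glba = cv$glba_ind, fish = cv$fish_ind)
}

capacity_design <- function(ls) {
  w <- ls$water
  need <- c("glba_ind", "fish_ind")
  miss <- setdiff(need, names(ls$covariates))
  if (length(miss))
    stop("landscape lacks covariates: ", paste(miss, collapse = ", "))
  cbind(intercept = 1, glba = ls$covariates$glba_ind[w],
        fish = ls$covariates$fish_ind[w])
}
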