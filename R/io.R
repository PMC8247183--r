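# Plain-text persistence: rasters as CSV grids, survey tables as CSV,
# configuration and standardization constants as YAML sidecars.  The package
# works on planar grids only, so no projection metadata is carried.

#' Read and write rasters as CSV grids
#'
#' A raster is stored as a headerless CSV of numbers with one row per grid
#' row; `NA` encodes land/undefined cells.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @return `read_grid_csv()` returns a numeric matrix.
#' @export
write_grid_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Persist a landscape as CSV grids with a YAML sidecar
#'
#' Writes one CSV per raster (`water.csv` plus one per covariate) and a
#' `landscape.yml` sidecar holding the cell size, town locations and the
#' standardization constants, so the exact scaling can be replayed on new
#' inputs.
#'
#' @param ls an [landscape()].
#' @param dir output directory (created if needed).
#' @return `read_landscape()` returns the reconstructed [landscape()].
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid_csv(ls$water * 1, file.path(dir, "water.csv"))
  for (nm in names(ls$covariates))
    write_grid_csv(ls$covariates[[nm]], file.path(dir, paste0(nm, ".csv")))
  meta <- list(cell_size = ls$cell_size,
               covariates = names(ls$covariates),
               standardization = lapply(ls$standardization, as.list),
               towns = if (!is.null(ls$towns)) as.list(ls$towns))
  yaml::write_yaml(meta, file.path(dir, "landscape.yml"))
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "landscape.yml"))
  water <- read_grid_csv(file.path(dir, "water.csv")) > 0
  covs <- lapply(meta$covariates, function(nm)
    read_grid_csv(file.path(dir, paste0(nm, ".csv"))))
  names(covs) <- meta$covariates
  std <- lapply(meta$standardization, function(x)
    c(mean = x$mean, sd = x$sd))
  towns <- if (!is.null(meta$towns)) as.data.frame(meta$towns)
  landscape(water, meta$cell_size, covs, towns = towns,
            standardization = std)
}

#' Persist survey data as CSV files
#'
#' Writes `counts.csv`, `true_counts.csv`, `isu.csv` and a `surveys.yml`
#' sidecar (photo years).
#'
#' @param surveys an [survey_data()].
#' @param dir output directory.
#' @return `read_surveys()` returns the reconstructed [survey_data()].
#' @export
write_surveys <- function(surveys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(surveys$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(surveys$true_counts, file.path(dir, "true_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(surveys$isu, file.path(dir, "isu.csv"), row.names = FALSE)
  yaml::write_yaml(list(photo_years = surveys$photo_years),
                   file.path(dir, "surveys.yml"))
  invisible(dir)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "surveys.yml"))
  survey_data(counts = utils::read.csv(file.path(dir, "counts.csv")),
              true_counts = utils::read.csv(file.path(dir, "true_counts.csv")),
              isu = utils::read.csv(file.path(dir, "isu.csv")),
              photo_years = as.numeric(unlist(meta$photo_years)))
}
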