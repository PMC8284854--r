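# Plain-text array containers: a CSV matrix plus a JSON sidecar carrying
# the geometry/provenance metadata, used for count data, reconstructions
# and kinetic maps.

#' Write/read a numeric array as CSV with a JSON sidecar
#'
#' The matrix is written as a plain CSV (no row names); metadata (grid
#' dimensions, scanner settings, schedule provenance, parameter names)
#' goes to `<file>.json`.
#'
#' @param x numeric matrix (e.g. bins x frames counts, voxels x
#'   parameters kinetic maps).
#' @param file CSV path; the sidecar is written to `paste0(file, ".json")`.
#' @param meta named list of metadata (serialised with jsonlite).
#' @export
write_array_csv <- function(x, file, meta = list()) {
  utils::write.table(as.matrix(x), file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta$dim <- dim(as.matrix(x))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_array_csv
#' @return for `read_array_csv`: the matrix with attribute `meta`.
#' @export
read_array_csv <- function(file) {
  x <- as.matrix(utils::read.table(file, sep = ","))
  dimnames(x) <- NULL
  side <- paste0(file, ".json")
  if (file.exists(side))
    attr(x, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  x
}

#' Write kinetic maps with a geometry sidecar
#'
#' Flattens the per-injection parameter maps of [nprm_map()] into one CSV
#' per injection, with a sidecar describing the grid and parameter order.
#'
#' @param maps result of [nprm_map()] or [true_kinetic_maps()].
#' @param prefix path prefix; files are `<prefix>_inj<j>.csv`.
#' @param geometry named list describing the voxel grid (e.g.
#'   `list(n = 128, dims = 1)`).
#' @export
write_kinetic_maps <- function(maps, prefix, geometry = list()) {
  for (j in seq_along(maps)) {
    f <- sprintf("%s_inj%d.csv", prefix, j)
    write_array_csv(maps[[j]], f,
                    meta = c(geometry,
                             list(parameters = colnames(maps[[j]]),
                                  injection = j)))
  }
  invisible(prefix)
}
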