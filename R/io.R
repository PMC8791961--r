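#' Read and write the package's plain-text interchange formats
#'
#' All tabular I/O is CSV: morphometrics as `subject_id` plus one column per
#' region; metadata with the columns of the subject-metadata schema (empty
#' cell = missing); atlases as `region_id, hemisphere, lobe, x, y, z,
#' mirror_of`; receptor maps as `region_id, bp`.
#'
#' @param values Subjects x regions matrix (rownames = subject ids).
#' @param path File path.
#' @param measure Measure kind stored on read ("thickness", "area", "volume").
#' @return Readers return the corresponding object; writers return the path,
#'   invisibly.
#' @name morph_io
NULL

#' @rdname morph_io
#' @export
write_morph_csv <- function(values, path) {
  assert_morph_table(values)
  df <- data.frame(subject_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname morph_io
#' @export
read_morph_csv <- function(path, measure = "thickness") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("morphometrics CSV must have a subject_id column", call. = FALSE)
  }
  values <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(values) <- df$subject_id
  storage.mode(values) <- "double"
  attr(values, "measure") <- measure
  assert_morph_table(values)
  values
}

#' @rdname morph_io
#' @param meta Metadata data.frame.
#' @export
write_meta_csv <- function(meta, path) {
  assert_metadata(meta)
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname morph_io
#' @export
read_meta_csv <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  assert_metadata(meta)
  meta
}

#' @rdname morph_io
#' @param atlas Atlas data.frame.
#' @export
write_atlas_csv <- function(atlas, path) {
  validate_atlas(atlas, symmetric = FALSE)
  utils::write.csv(
    atlas[, c("region_id", "hemisphere", "lobe", "x", "y", "z", "mirror_of")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname morph_io
#' @export
read_atlas_csv <- function(path) {
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(atlas) <- c("atlas", "data.frame")
  validate_atlas(atlas, symmetric = FALSE)
  atlas
}

#' @rdname morph_io
#' @param map Receptor map data.frame (`region_id`, `bp`).
#' @export
write_receptor_csv <- function(map, path) {
  stopifnot(all(c("region_id", "bp") %in% names(map)))
  utils::write.csv(map[, c("region_id", "bp")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname morph_io
#' @param receptor_label Label attached to the map on read.
#' @export
read_receptor_csv <- function(path, receptor_label = NULL) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "bp") %in% names(map)))
  attr(map, "receptor_label") <- receptor_label %||% basename(path)
  map
}

#' @rdname morph_io
#' @param truth A [cohort_truth()] object.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "cohort_truth"))
  x <- unclass(truth)
  x$loadings <- lapply(x$loadings, function(L) {
    list(regions = rownames(L), values = unname(L))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
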