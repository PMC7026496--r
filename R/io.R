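#' Read and write the pipeline's flat-file formats
#'
#' Thin readr wrappers around the dialects the simulators emit: screen
#' plate CSV (plate, well, compound_id, role, replicate, luminescence),
#' compound annotation CSV (compound_id, target, pathway), site-level
#' abundance TSV (protein, site, sample, group, abundance), and growth CSV
#' (animal, arm, day, length_mm, width_mm).
#'
#' @param path File path.
#' @return A tibble (readers); `path` invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_screen_plates <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plate = "c", well = "c", compound_id = "c", role = "c",
    replicate = "i", luminescence = "d"
  ))
}

#' @rdname pipeline_io
#' @param x Tibble to write.
#' @export
write_screen_plates <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_compound_annotations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = "c"))
}

#' @rdname pipeline_io
#' @export
read_abundance_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein = "c", site = "c", sample = "c", group = "c", abundance = "d"
  ))
}

#' @rdname pipeline_io
#' @export
write_abundance_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_growth_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal = "c", arm = "c", day = "d", length_mm = "d", width_mm = "d"
  ))
}

#' @rdname pipeline_io
#' @export
write_growth_records <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
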