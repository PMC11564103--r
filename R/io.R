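# Tabular IO for the screening tables.

#' Read a cell-level well table
#'
#' TSV/CSV with one row per segmented cell; required columns are
#' `cell_id`, `plate_id`, `well_id`, `drug_name`, `concentration_um`,
#' `replicate` plus either boolean marker gates (`nestin`, `s100b`,
#' `cd45`) or `intensity_*` channels, optionally `patient_id` and
#' `apoptotic`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_well_cells <- function(path) {
  tbl <- if (grepl("\\.csv$", path)) readr::read_csv(path, show_col_types = FALSE)
         else readr::read_tsv(path, show_col_types = FALSE)
  required <- c("cell_id", "plate_id", "well_id", "drug_name",
                "concentration_um", "replicate")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("well table misses required columns: %s",
                  paste(missing, collapse = ", ")))
  }
  tbl
}

#' Write drug responses or other result tibbles as TSV
#'
#' @param x Tibble.
#' @param path Output path.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
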