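#' Read a bioactivity table
#'
#' Expects the drug-target-commons-style columns `compound_id`,
#' `gene_symbol`, `endpoint_type` and optionally `value`; endpoint types
#' are uppercased on ingest.
#'
#' @param path TSV/CSV file path.
#' @return Tibble.
#' @export
read_bioactivity <- function(path) {
  tbl <- if (grepl("\\.csv$", path)) readr::read_csv(path, show_col_types = FALSE)
         else readr::read_tsv(path, show_col_types = FALSE)
  ingest_bioactivity(tbl)
}

#' @rdname read_bioactivity
#' @param tbl In-memory bioactivity table.
#' @export
ingest_bioactivity <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("compound_id", "gene_symbol", "endpoint_type") %in% names(tbl)))
  if (anyNA(tbl$compound_id) || anyNA(tbl$gene_symbol)) {
    abort("bioactivity table has null compound or gene ids")
  }
  tbl$endpoint_type <- toupper(tbl$endpoint_type)
  tbl
}

#' Read a protein-protein interaction table
#'
#' Expects `gene_a`, `gene_b`, `score`.  Scores on the 0-999 STRING
#' dialect (detected by a maximum above 1) are rescaled to \[0, 1\].
#' The table is symmetrised, self-loops are dropped, and duplicate
#' pairs keep the maximum score.
#'
#' @param path TSV file path.
#' @return Tibble with canonicalised pairs (both orientations present).
#' @export
read_ppi <- function(path) {
  ingest_ppi(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_ppi
#' @param tbl In-memory PPI table.
#' @export
ingest_ppi <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(tbl)))
  if (max(tbl$score, na.rm = TRUE) > 1) tbl$score <- tbl$score / 1000
  check_prob(tbl$score, "ppi score")
  tbl <- tbl[tbl$gene_a != tbl$gene_b, ]
  both <- dplyr::bind_rows(tbl,
                           tibble::tibble(gene_a = tbl$gene_b,
                                          gene_b = tbl$gene_a,
                                          score = tbl$score))
  both |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Primary target genes of each compound
#'
#' PTGs are genes with at least one bioactivity record whose endpoint
#' standard type is the inhibitory constant `KI`.
#'
#' @param bio Bioactivity table (see [ingest_bioactivity()]).
#' @return Distinct tibble (compound_id, gene_symbol).
#' @export
extract_ptgs <- function(bio) {
  bio <- ingest_bioactivity(bio)
  dplyr::distinct(bio[bio$endpoint_type == "KI", c("compound_id", "gene_symbol")]) |>
    dplyr::arrange(.data$compound_id, .data$gene_symbol)
}

#' Extended primary target genes of each compound
#'
#' ePTGs include every gene with *any* bioactivity annotation, so
#' `PTG(d)` is a subset of `ePTG(d)` for every drug.
#'
#' @inheritParams extract_ptgs
#' @return Distinct tibble (compound_id, gene_symbol).
#' @export
extract_eptgs <- function(bio) {
  bio <- ingest_bioactivity(bio)
  dplyr::distinct(bio[, c("compound_id", "gene_symbol")]) |>
    dplyr::arrange(.data$compound_id, .data$gene_symbol)
}

#' Expand ePTGs to secondary target genes via high-confidence PPIs
#'
#' `STG(e)` is every gene linked to ePTG `e` by an interaction with
#' score at or above `min_score` (inclusive threshold; 0.6 by default,
#' the high-confidence cut), excluding self-loops.
#'
#' @param eptgs Either a character vector of ePTG gene symbols or a
#'   (compound_id, gene_symbol) tibble from [extract_eptgs()].
#' @param ppi Symmetrised PPI tibble from [ingest_ppi()].
#' @param min_score Inclusive interaction-score threshold in \[0, 1\].
#' @return Tibble (eptg, stg).
#' @export
expand_stgs <- function(eptgs, ppi, min_score = 0.6) {
  if (min_score < 0 || min_score > 1) abort("`min_score` must be in [0, 1]")
  genes <- if (is.data.frame(eptgs)) unique(eptgs$gene_symbol) else unique(eptgs)
  kept <- ppi[ppi$score >= min_score, ]
  out <- kept[kept$gene_a %in% genes & kept$gene_a != kept$gene_b,
              c("gene_a", "gene_b")]
  names(out) <- c("eptg", "stg")
  dplyr::arrange(dplyr::distinct(out), .data$eptg, .data$stg)
}

#' Build the drug x STG integrated-connectivity feature matrix
#'
#' Integrated connectivity of drug `d` to secondary target `g` counts
#' the distinct ePTG paths: `X[d, g] = |{e in ePTG(d) : g in STG(e)}|`
#' (`mode = "path_count"`); `mode = "binary"` keeps the indicator
#' `X > 0`.  STG columns with no connectivity to any drug are dropped;
#' rows and columns are sorted lexicographically; drugs with no ePTG
#' annotation keep an all-zero row and are flagged in `unannotated`.
#'
#' @param drug_eptg Tibble (compound_id, gene_symbol) of ePTG
#'   annotations.
#' @param eptg_stg Tibble (eptg, stg) from [expand_stgs()].
#' @param mode `"path_count"` or `"binary"`.
#' @param drugs Optional character vector of all drugs to include
#'   (retains unannotated drugs as all-zero rows).
#' @param ppi_threshold Threshold recorded in the result.
#' @return A `constellation` object: list with `X` (sparse dgCMatrix),
#'   `drugs`, `eptgs`, `stgs`, `drug_eptg`, `eptg_stg`, `mode`,
#'   `ppi_threshold`, `unannotated`.
#' @export
build_feature_matrix <- function(drug_eptg, eptg_stg,
                                 mode = c("path_count", "binary"),
                                 drugs = NULL, ppi_threshold = 0.6) {
  mode <- match.arg(mode)
  drug_eptg <- dplyr::distinct(tibble::as_tibble(drug_eptg))
  eptg_stg <- dplyr::distinct(tibble::as_tibble(eptg_stg))
  if (is.null(drugs)) drugs <- sort(unique(drug_eptg$compound_id))
  else drugs <- sort(unique(drugs))
  eptgs <- sort(unique(c(drug_eptg$gene_symbol, eptg_stg$eptg)))
  stgs <- sort(unique(eptg_stg$stg))
  if (length(drugs) == 0 || length(stgs) == 0) {
    abort("no drugs or no STGs after filtering")
  }
  D <- Matrix::sparseMatrix(
    i = match(drug_eptg$compound_id, drugs),
    j = match(drug_eptg$gene_symbol, eptgs),
    x = 1, dims = c(length(drugs), length(eptgs)),
    dimnames = list(drugs, eptgs))
  E <- Matrix::sparseMatrix(
    i = match(eptg_stg$eptg, eptgs),
    j = match(eptg_stg$stg, stgs),
    x = 1, dims = c(length(eptgs), length(stgs)),
    dimnames = list(eptgs, stgs))
  X <- D %*% E
  keep <- Matrix::colSums(X) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) abort("no drugs or no STGs after filtering")
  if (mode == "binary") X@x <- rep(1, length(X@x))
  X <- methods::as(methods::as(X, "generalMatrix"), "CsparseMatrix")
  structure(
    list(X = X, drugs = drugs, eptgs = eptgs, stgs = colnames(X),
         drug_eptg = drug_eptg, eptg_stg = eptg_stg, mode = mode,
         ppi_threshold = ppi_threshold,
         unannotated = setdiff(drugs, unique(drug_eptg$compound_id))),
    class = "constellation")
}

#' Build a constellation from bioactivity and PPI tables
#'
#' Convenience chain: [extract_eptgs()] -> [expand_stgs()] ->
#' [build_feature_matrix()].
#'
#' @param bio Bioactivity table.
#' @param ppi PPI table (raw; ingested internally).
#' @param min_score Inclusive PPI score threshold.
#' @param mode Connectivity mode (see [build_feature_matrix()]).
#' @param drugs Optional full drug list (keeps unannotated drugs).
#' @return A `constellation` object.
#' @export
build_constellation <- function(bio, ppi, min_score = 0.6,
                                mode = c("path_count", "binary"),
                                drugs = NULL) {
  mode <- match.arg(mode)
  eptgs <- extract_eptgs(bio)
  ppi <- ingest_ppi(ppi)
  links <- expand_stgs(eptgs, ppi, min_score)
  build_feature_matrix(eptgs, links, mode = mode, drugs = drugs,
                       ppi_threshold = min_score)
}

#' @export
print.constellation <- function(x, ...) {
  cat(sprintf(
    "<constellation> %d drugs, %d ePTGs, %d STG features (%s, PPI >= %.2f)\n",
    length(x$drugs), length(unique(x$drug_eptg$gene_symbol)),
    length(x$stgs), x$mode, x$ppi_threshold))
  if (length(x$unannotated)) {
    cat(sprintf("  %d unannotated drugs (all-zero rows)\n", length(x$unannotated)))
  }
  invisible(x)
}

#' Serialize a constellation to JSON
#'
#' Stored as vocabularies plus sparse (row, col, value) triplets, so a
#' written constellation re-ingests bit-exactly.
#'
#' @param x A `constellation`.
#' @param path Output JSON path.
#' @export
write_constellation <- function(x, path) {
  stopifnot(inherits(x, "constellation"))
  trip <- Matrix::summary(x$X)
  obj <- list(
    schema = "neurocostar-constellation-1",
    mode = x$mode, ppi_threshold = x$ppi_threshold,
    drugs = x$drugs, stgs = x$stgs, eptgs = x$eptgs,
    unannotated = x$unannotated,
    x_i = as.integer(trip$i), x_j = as.integer(trip$j), x_v = trip$x,
    drug_eptg = x$drug_eptg, eptg_stg = x$eptg_stg)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_constellation
#' @return `read_constellation()` returns the `constellation` object.
#' @export
read_constellation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- Matrix::sparseMatrix(i = obj$x_i, j = obj$x_j, x = obj$x_v,
                            dims = c(length(obj$drugs), length(obj$stgs)),
                            dimnames = list(obj$drugs, obj$stgs))
  structure(
    list(X = methods::as(methods::as(X, "generalMatrix"), "CsparseMatrix"),
         drugs = obj$drugs, eptgs = obj$eptgs, stgs = obj$stgs,
         drug_eptg = tibble::as_tibble(obj$drug_eptg),
         eptg_stg = tibble::as_tibble(obj$eptg_stg),
         mode = obj$mode, ppi_threshold = obj$ppi_threshold,
         unannotated = as.character(unlist(obj$unannotated))),
    class = "constellation")
}
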