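# Expressing-fraction specificity scores from single-cell counts.

#' Read a gene x cell count matrix in MTX format
#'
#' Expects the usual triplet layout: `matrix.mtx`, `genes.tsv` (one
#' gene symbol per line, first column) and `barcodes.tsv`/`cells.tsv`.
#'
#' @param dir Directory containing the three files.
#' @return Sparse dgCMatrix with gene rownames and cell colnames.
#' @export
read_mtx_counts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           col_names = FALSE, show_col_types = FALSE)
  bc_file <- file.path(dir, "barcodes.tsv")
  if (!file.exists(bc_file)) bc_file <- file.path(dir, "cells.tsv")
  cells <- readr::read_tsv(bc_file, col_names = FALSE, show_col_types = FALSE)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  dimnames(m) <- list(genes[[1]], cells[[1]])
  m
}

#' Per-gene, per-patient, per-class expressing fractions
#'
#' A cell expresses a gene either when its count is nonzero
#' (`mode = "nonzero"`, the definition under which the specificity
#' scores are stated) or when `log2(count + 1) > tau`
#' (`mode = "threshold"`; tau = 3 means count > 7), the per-dataset
#' convention of the marker-panel analyses.
#'
#' @param counts Gene x cell count matrix (sparse or dense) with
#'   dimnames.
#' @param metadata Tibble with `cell_id`, `patient_id`,
#'   `lineage_class` (`"neural"`/`"immune"`) covering every column of
#'   `counts`.
#' @param mode `"nonzero"` or `"threshold"`.
#' @param tau Expression threshold on `log2(count + 1)`
#'   (`mode = "threshold"`).
#' @return Tibble: gene, patient_id, lineage_class, n_cells,
#'   n_positive, fraction.
#' @export
expressing_fractions <- function(counts, metadata,
                                 mode = c("nonzero", "threshold"), tau = 3) {
  mode <- match.arg(mode)
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("cell_id", "patient_id", "lineage_class") %in% names(metadata)))
  if (nrow(counts) == 0 || ncol(counts) == 0) abort("zero genes or cells")
  if (is.null(colnames(counts))) abort("`counts` needs cell ids as colnames")
  metadata <- metadata[match(colnames(counts), metadata$cell_id), ]
  if (anyNA(metadata$patient_id) || anyNA(metadata$lineage_class)) {
    abort("every cell needs a patient and lineage class")
  }
  if (mode == "threshold" && tau <= 0) abort("`tau` must be > 0")
  cut <- if (mode == "nonzero") 0 else 2^tau - 1  # expressed iff count > cut

  m <- methods::as(counts, "CsparseMatrix")
  pos <- m
  pos@x <- as.numeric(pos@x > cut)
  pos <- Matrix::drop0(pos)

  stratum <- interaction(metadata$patient_id, metadata$lineage_class,
                         drop = FALSE, sep = "\r")
  # indicator matrix cells x strata for fast per-stratum positives
  G <- Matrix::sparseMatrix(i = seq_len(ncol(m)),
                            j = as.integer(stratum),
                            x = 1, dims = c(ncol(m), nlevels(stratum)))
  n_pos <- as.matrix(pos %*% G)
  n_cells <- as.integer(table(factor(stratum, levels = levels(stratum))))
  parts <- strsplit(levels(stratum), "\r", fixed = TRUE)
  strata <- tibble::tibble(patient_id = vapply(parts, `[`, "", 1),
                           lineage_class = vapply(parts, `[`, "", 2),
                           n_cells = n_cells)
  out <- tidyr::expand_grid(gene = rownames(m), idx = seq_len(nrow(strata)))
  out <- dplyr::bind_cols(out, strata[out$idx, ])
  out$n_positive <- as.integer(t(n_pos))[seq_len(nrow(out))]
  out$fraction <- ifelse(out$n_cells > 0, out$n_positive / out$n_cells, NA_real_)
  if (any(out$n_cells == 0)) warn("strata with 0 cells give missing fractions")
  dplyr::select(out, -"idx")
}

#' Neural specificity score per gene
#'
#' Cohort-level difference of pooled expressing fractions: the fraction
#' of neural-lineage cells expressing a gene minus the fraction of
#' immune cells expressing it, pooling cells across patients.  Ranges
#' from -1 (all immune, no neural) to +1 (all neural, no immune); low
#' expression pushes the score toward 0.
#'
#' @param fractions Output of [expressing_fractions()].
#' @return Tibble: gene, fraction_neural, fraction_immune,
#'   neural_specificity.
#' @export
neural_specificity <- function(fractions) {
  pooled <- fractions |>
    dplyr::group_by(.data$gene, .data$lineage_class) |>
    dplyr::summarise(n_positive = sum(.data$n_positive),
                     n_cells = sum(.data$n_cells), .groups = "drop") |>
    dplyr::mutate(fraction = ifelse(.data$n_cells > 0,
                                    .data$n_positive / .data$n_cells, NA_real_))
  wide <- tidyr::pivot_wider(pooled[, c("gene", "lineage_class", "fraction")],
                             names_from = "lineage_class",
                             values_from = "fraction", names_prefix = "fraction_")
  for (cl in c("fraction_neural", "fraction_immune")) {
    if (!cl %in% names(wide)) {
      warn(sprintf("class '%s' absent: neural specificity is NA",
                   sub("fraction_", "", cl)))
      wide[[cl]] <- NA_real_
    }
  }
  wide$neural_specificity <- wide$fraction_neural - wide$fraction_immune
  wide[, c("gene", "fraction_neural", "fraction_immune", "neural_specificity")]
}

#' Patient specificity score per gene
#'
#' For each patient the composition-independent expressing fraction is
#' `Fraction_expressing = fraction_immune + fraction_neural` (range
#' \[0, 2\]: summing the two per-class fractions removes the dependence
#' on each patient's immune/neural cell mix).  Patient specificity is
#' the unscaled median absolute deviation of `Fraction_expressing`
#' across patients (MAD of values in \[0, 2\] is at most 1).
#'
#' @param fractions Output of [expressing_fractions()].
#' @param eligible Optional eligibility tibble from
#'   [filter_eligible()]; when supplied, only eligible (gene, patient)
#'   pairs enter the MAD.
#' @return Tibble: gene, n_patients, patient_specificity (NA when
#'   fewer than 2 contributing patients).
#' @export
patient_specificity <- function(fractions, eligible = NULL) {
  per_patient <- fractions |>
    tidyr::pivot_wider(id_cols = c("gene", "patient_id"),
                       names_from = "lineage_class", values_from = "fraction")
  for (cl in c("immune", "neural")) {
    if (!cl %in% names(per_patient)) per_patient[[cl]] <- NA_real_
  }
  per_patient <- dplyr::mutate(per_patient,
                               fraction_expressing = .data$immune + .data$neural)
  if (!is.null(eligible)) {
    per_patient <- dplyr::inner_join(
      per_patient, eligible[eligible$eligible, c("gene", "patient_id")],
      by = c("gene", "patient_id"))
  }
  per_patient |>
    dplyr::filter(!is.na(.data$fraction_expressing)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      patient_specificity = if (dplyr::n() >= 2)
        mad(.data$fraction_expressing, constant = 1) else NA_real_,
      .groups = "drop")
}

#' Patient eligibility per gene
#'
#' A patient sample counts for a gene only when it contributes more
#' than `min_positive` positive cells (strict inequality), summed over
#' both lineage classes.  The flag changes patient inclusion only; it
#' never alters the per-patient fraction values.
#'
#' @param fractions Output of [expressing_fractions()].
#' @param min_positive Strict positive-cell cutoff.
#' @return Tibble: gene, patient_id, n_positive, eligible.
#' @export
filter_eligible <- function(fractions, min_positive = 50) {
  fractions |>
    dplyr::group_by(.data$gene, .data$patient_id) |>
    dplyr::summarise(n_positive = sum(.data$n_positive), .groups = "drop") |>
    dplyr::mutate(eligible = .data$n_positive > min_positive)
}

#' Gene specificity table
#'
#' One-stop wrapper: expressing fractions, cohort-level neural
#' specificity, patient specificity (over eligible patients when
#' `apply_eligibility` is set) and overall percent expressing.
#'
#' @inheritParams expressing_fractions
#' @param min_positive Eligibility cutoff (see [filter_eligible()]).
#' @param apply_eligibility Restrict the patient-specificity MAD to
#'   eligible patients.
#' @return Tibble: gene, fraction_neural, fraction_immune,
#'   neural_specificity, patient_specificity, n_patients,
#'   pct_expressing.
#' @export
gene_specificity <- function(counts, metadata,
                             mode = c("nonzero", "threshold"), tau = 3,
                             min_positive = 50, apply_eligibility = TRUE) {
  mode <- match.arg(mode)
  fr <- expressing_fractions(counts, metadata, mode = mode, tau = tau)
  ns <- neural_specificity(fr)
  elig <- if (apply_eligibility) filter_eligible(fr, min_positive) else NULL
  ps <- patient_specificity(fr, eligible = elig)
  overall <- fr |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(pct_expressing = 100 * sum(.data$n_positive) / sum(.data$n_cells),
                     .groups = "drop")
  ns |>
    dplyr::left_join(ps, by = "gene") |>
    dplyr::left_join(overall, by = "gene")
}
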