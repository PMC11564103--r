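#' Configuration for a simulated single-cell expression matrix
#'
#' Emulates a patient- and lineage-structured scRNA-seq count matrix.
#' Genes belong to one of five classes with target expressing
#' probabilities per lineage class:
#'
#' * `neural_specific` — high in neural cells, absent in immune cells;
#' * `immune_specific` — the mirror image;
#' * `pan` — expressed at the same moderate rate everywhere;
#' * `patient_variable` — per-patient expressing probability drawn once
#'   per patient (shared by both lineages);
#' * `silent` — never expressed.
#'
#' The expressed/unexpressed indicator is planted exactly: expressed
#' cells draw counts of at least 8 (above the `log2(count+1) > 3`
#' threshold), unexpressed cells get 0, so expressing fractions are
#' Bernoulli with exactly the target probability under both the nonzero
#' and the threshold definition of expression.
#'
#' @param n_genes Total number of genes, split across classes by
#'   `class_weights`.
#' @param n_cells_per_patient Cells per patient.
#' @param n_patients Number of patients.
#' @param class_mix Probability that a cell is neural (vs immune).
#' @param class_weights Named weights for the five gene classes.
#' @param p_neural,p_immune Expressing probabilities of a
#'   `neural_specific` gene in neural/immune cells (`immune_specific`
#'   mirrors them; `pan` uses `p_pan` in both).
#' @param p_pan Expressing probability of `pan` genes.
#' @param patient_variable_range Range the per-patient expressing
#'   probability of `patient_variable` genes is drawn from.
#' @param nb_mean,nb_dispersion Negative-binomial mean/dispersion of the
#'   expressed-cell count magnitude (added on top of the count floor 8).
#' @param seed Integer master seed.
#' @return A list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 250,
                            n_cells_per_patient = 1000,
                            n_patients = 10,
                            class_mix = 0.6,
                            class_weights = c(neural_specific = 1, immune_specific = 1,
                                              pan = 2, patient_variable = 2, silent = 4),
                            p_neural = 0.9,
                            p_immune = 0,
                            p_pan = 0.6,
                            patient_variable_range = c(0.2, 0.9),
                            nb_mean = 20,
                            nb_dispersion = 0.5,
                            seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_cells_per_patient <- check_count(n_cells_per_patient, "n_cells_per_patient")
  n_patients <- check_count(n_patients, "n_patients")
  check_prob(c(class_mix, p_neural, p_immune, p_pan, patient_variable_range),
             "expressing probabilities")
  structure(
    list(n_genes = n_genes, n_cells_per_patient = n_cells_per_patient,
         n_patients = n_patients, class_mix = class_mix,
         class_weights = class_weights, p_neural = p_neural,
         p_immune = p_immune, p_pan = p_pan,
         patient_variable_range = patient_variable_range,
         nb_mean = nb_mean, nb_dispersion = nb_dispersion,
         seed = as.integer(seed)),
    class = "expr_sim_config"
  )
}

#' Simulate a gene x cell count matrix with planted gene classes
#'
#' @param config An [expr_sim_config()].
#' @return A list with `counts` (sparse dgCMatrix, genes x cells),
#'   `metadata` (tibble: cell_id, patient_id, lineage_class) and
#'   `gene_classes` (tibble: gene, class, and the planted per-class
#'   expressing probabilities `p_neural`, `p_immune`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  if (config$n_genes < 1 || config$n_cells_per_patient < 1) {
    abort("zero genes or cells requested")
  }
  set.seed(substream_seed(config$seed, 0L))

  classes <- names(config$class_weights)
  n_per <- floor(config$n_genes * config$class_weights / sum(config$class_weights))
  n_per[1] <- n_per[1] + config$n_genes - sum(n_per)
  gene_class <- rep(classes, n_per)
  genes <- sprintf("G%04d", seq_len(config$n_genes))

  patients <- sprintf("P%02d", seq_len(config$n_patients))
  n_cells <- config$n_cells_per_patient * config$n_patients
  meta <- tibble::tibble(
    cell_id = sprintf("cell%06d", seq_len(n_cells)),
    patient_id = rep(patients, each = config$n_cells_per_patient),
    lineage_class = ifelse(runif(n_cells) < config$class_mix, "neural", "immune")
  )

  # Per-gene, per-patient, per-lineage expressing probabilities.
  pv_range <- config$patient_variable_range
  p_patient_var <- matrix(runif(config$n_genes * config$n_patients,
                                pv_range[1], pv_range[2]),
                          nrow = config$n_genes)

  patient_idx <- match(meta$patient_id, patients)
  is_neural <- meta$lineage_class == "neural"
  cell_probs <- function(g) {
    switch(gene_class[g],
      neural_specific = ifelse(is_neural, config$p_neural, config$p_immune),
      immune_specific = ifelse(is_neural, config$p_immune, config$p_neural),
      pan = rep(config$p_pan, n_cells),
      patient_variable = p_patient_var[g, patient_idx],
      silent = rep(0, n_cells))
  }

  i <- integer(0); j <- integer(0); x <- integer(0)
  for (g in seq_len(config$n_genes)) {
    set.seed(substream_seed(config$seed, g))
    expressed <- runif(n_cells) < cell_probs(g)
    idx <- which(expressed)
    if (length(idx)) {
      counts <- 8L + rnbinom(length(idx), mu = config$nb_mean,
                             size = 1 / config$nb_dispersion)
      i <- c(i, rep.int(g, length(idx))); j <- c(j, idx); x <- c(x, counts)
    }
  }
  counts <- Matrix::sparseMatrix(i = i, j = j, x = x,
                                 dims = c(config$n_genes, n_cells),
                                 dimnames = list(genes, meta$cell_id))
  class_p <- list(
    neural_specific = c(config$p_neural, config$p_immune),
    immune_specific = c(config$p_immune, config$p_neural),
    pan = c(config$p_pan, config$p_pan),
    silent = c(0, 0)
  )
  pn <- pi_ <- numeric(config$n_genes)
  for (g in seq_len(config$n_genes)) {
    if (gene_class[g] == "patient_variable") {
      pn[g] <- pi_[g] <- mean(p_patient_var[g, ])
    } else {
      pn[g] <- class_p[[gene_class[g]]][1]
      pi_[g] <- class_p[[gene_class[g]]][2]
    }
  }
  gene_classes <- tibble::tibble(gene = genes, class = gene_class,
                                 p_neural = pn, p_immune = pi_)
  list(counts = counts, metadata = meta, gene_classes = gene_classes)
}
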