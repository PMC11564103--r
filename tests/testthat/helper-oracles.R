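# Independent oracles used across the suite.  Each recomputes a result
# by the most literal route available (counting, enumeration, plain
# gradient descent) and never calls the code path it checks.

# Brute-force PCY: count cells well by well, average fractions per
# drug, subtract.  Works directly on a classified cell table.
oracle_pcy <- function(cells, target = "glioblastoma") {
  wells <- split(cells, cells$well_id)
  frac <- vapply(wells, function(w) mean(w$population == target), numeric(1))
  drug_of <- vapply(wells, function(w) w$drug_name[1], character(1))
  dmso <- mean(frac[drug_of == "DMSO"])
  drugs <- setdiff(unique(drug_of), "DMSO")
  tibble::tibble(
    drug_name = drugs,
    pcy_score = vapply(drugs, function(d)
      1 - mean(frac[drug_of == d]) / dmso, numeric(1), USE.NAMES = FALSE))
}

# Exhaustive path enumeration: for every (drug, stg) pair, count ePTGs
# of the drug that have a qualifying edge to the stg.
oracle_path_counts <- function(bio, ppi, min_score = 0.6) {
  ann <- unique(bio[, c("compound_id", "gene_symbol")])
  ppi2 <- rbind(ppi, data.frame(gene_a = ppi$gene_b, gene_b = ppi$gene_a,
                                score = ppi$score))
  agg <- stats::aggregate(score ~ gene_a + gene_b, ppi2, max)
  agg <- agg[agg$score >= min_score & agg$gene_a != agg$gene_b, ]
  drugs <- sort(unique(ann$compound_id))
  stgs <- sort(unique(agg$gene_b))
  X <- matrix(0L, length(drugs), length(stgs), dimnames = list(drugs, stgs))
  for (d in drugs) {
    eptgs <- ann$gene_symbol[ann$compound_id == d]
    for (e in eptgs) {
      targets <- agg$gene_b[agg$gene_a == e]
      X[d, targets] <- X[d, targets] + 1L
    }
  }
  X[, colSums(X) > 0, drop = FALSE]
}

# Proximal-gradient (ISTA) solver for the same penalized logistic
# objective, run to a tight tolerance; the reference optimizer for
# coefficient agreement checks.
oracle_prox_logistic <- function(X, y, lambda, tol = 1e-10, max_iter = 2e5) {
  n <- nrow(X)
  b0 <- 0
  b <- rep(0, ncol(X))
  L <- (max(svd(cbind(1, X))$d)^2) / (4 * n)
  for (it in seq_len(max_iter)) {
    eta <- b0 + X %*% b
    mu <- stats::plogis(eta)
    g0 <- mean(mu - y)
    g <- crossprod(X, mu - y) / n
    b0n <- b0 - g0 / L
    bn <- b - g / L
    bn <- sign(bn) * pmax(abs(bn) - lambda / L, 0)
    conv <- max(abs(c(b0n - b0, bn - b))) < tol
    b0 <- b0n
    b <- as.numeric(bn)
    if (conv) break
  }
  list(beta0 = b0, beta = b)
}

# Exact permutation test over all group splits for a two-sample
# comparison of means (one-tailed: group a smaller).
oracle_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  splits <- utils::combn(length(pooled), na)
  obs <- mean(a) - mean(b)
  stat <- apply(splits, 2, function(idx) mean(pooled[idx]) - mean(pooled[-idx]))
  mean(stat <= obs + 1e-12)
}

# Random small well table with arbitrary population structure, for
# oracle-equivalence checks.
random_well_table <- function(seed, n_drugs = 3, max_cells = 40) {
  set.seed(seed)
  wells <- list()
  id <- 0
  for (d in c("DMSO", sprintf("d%02d", seq_len(n_drugs)))) {
    for (w in seq_len(if (d == "DMSO") 4 else 3)) {
      id <- id + 1
      n <- sample(5:max_cells, 1)
      pop <- sample(c("glioblastoma", "immune", "other"), n, replace = TRUE,
                    prob = runif(3) + 0.2)
      nestin <- pop == "glioblastoma" & runif(n) < 0.8
      s100b <- pop == "glioblastoma" & !nestin | (pop == "glioblastoma" & runif(n) < 0.5)
      wells[[id]] <- tibble::tibble(
        cell_id = sprintf("w%d_c%d", id, seq_len(n)),
        plate_id = "p1", well_id = sprintf("w%03d", id), drug_name = d,
        concentration_um = if (d == "DMSO") 0 else 10, replicate = w,
        patient_id = "P001",
        nestin = nestin, s100b = s100b, cd45 = pop == "immune")
    }
  }
  dplyr::bind_rows(wells)
}

# Tiny fully-determined count matrix: 2 patients x 2 lineages x 3 cells,
# 4 genes with known expression patterns.
toy_counts <- function() {
  meta <- tidyr::expand_grid(patient_id = c("P1", "P2"),
                             lineage_class = c("neural", "immune"),
                             rep = 1:3)
  meta$cell_id <- sprintf("c%02d", seq_len(nrow(meta)))
  m <- matrix(0, 4, nrow(meta),
              dimnames = list(c("gAllNeural", "gAllImmune", "gHalf", "gZero"),
                              meta$cell_id))
  m["gAllNeural", meta$lineage_class == "neural"] <- 10
  m["gAllImmune", meta$lineage_class == "immune"] <- 10
  m["gHalf", meta$cell_id %in% meta$cell_id[meta$rep <= 2]] <- 5
  list(counts = Matrix::Matrix(m, sparse = TRUE), metadata = meta)
}
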