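#' Configuration for a simulated drug-target network
#'
#' Emulates the inputs of the connectivity-signature learner: a
#' bioactivity table (drug -> extended primary target gene, ePTG), a
#' protein-protein-interaction table linking ePTGs to secondary target
#' genes (STGs) and binary hit labels.  A planted subset of STGs
#' carries the signature: `n_hits` designated drugs are wired to the
#' planted STGs through their own ePTG annotations (every designated
#' drug gets at least one planted path, every planted STG is wired to
#' `planted_drugs_per_stg` designated drugs), and labels are drawn
#' Bernoulli with `P(hit) = sigmoid(a * k + b)` where `k` is a drug's
#' realized integrated connectivity (number of distinct ePTG paths) to
#' the planted set.
#'
#' The defaults mirror the screening study's shape — 127 drugs with 30
#' expected hits — under a saturating label law (a = 50, b = -25), so
#' any planted connectivity makes a drug a near-certain hit ("strong
#' effect") while background PPI edges add occasional accidental
#' planted paths.
#'
#' @param n_drugs Number of labelled drugs.
#' @param n_eptg Size of the ePTG gene pool drugs annotate into.
#' @param n_stg Number of candidate secondary target genes.
#' @param n_planted_stg Number of STGs carrying the planted signature.
#' @param n_hits Number of designated signature-carrying drugs.
#' @param planted_drugs_per_stg Designated drugs wired to each planted
#'   STG (scores drawn above the 0.6 interaction threshold).
#' @param degree_exponent,degree_min,degree_max Truncated power law for
#'   the number of ePTG annotations per drug.
#' @param ppi_edge_prob Background edge probability between any pool
#'   ePTG and any STG; background scores are Uniform(0, 1) so a 0.6
#'   threshold keeps ~40% of background edges.
#' @param label_slope,label_intercept Parameters a, b of the label law
#'   `P(hit) = sigmoid(a * k + b)`.
#' @param seed Integer master seed.
#' @return A list of class `network_sim_config`.
#' @export
network_sim_config <- function(n_drugs = 127,
                               n_eptg = 3000,
                               n_stg = 1000,
                               n_planted_stg = 20,
                               n_hits = 30,
                               planted_drugs_per_stg = 2,
                               degree_exponent = 2,
                               degree_min = 1,
                               degree_max = 50,
                               ppi_edge_prob = 0.001,
                               label_slope = 50,
                               label_intercept = -25,
                               seed = 1L) {
  n_drugs <- check_count(n_drugs, "n_drugs")
  n_eptg <- check_count(n_eptg, "n_eptg")
  n_stg <- check_count(n_stg, "n_stg")
  n_planted_stg <- check_count(n_planted_stg, "n_planted_stg", min = 0)
  n_hits <- check_count(n_hits, "n_hits", min = 0)
  planted_drugs_per_stg <- check_count(planted_drugs_per_stg, "planted_drugs_per_stg")
  check_prob(ppi_edge_prob, "ppi_edge_prob")
  if (n_planted_stg > n_stg) abort("`n_planted_stg` must be <= `n_stg`")
  if (n_hits > n_drugs) abort("`n_hits` must be <= `n_drugs`")
  if (n_planted_stg == 0 && label_slope != 0) {
    abort("`n_planted_stg` = 0 with a nonzero `label_slope` leaves labels undefined")
  }
  if (n_planted_stg > 0 && n_hits == 0) {
    abort("`n_hits` must be >= 1 when a signature is planted")
  }
  structure(
    list(n_drugs = n_drugs, n_eptg = n_eptg, n_stg = n_stg,
         n_planted_stg = n_planted_stg, n_hits = n_hits,
         planted_drugs_per_stg = planted_drugs_per_stg,
         degree_exponent = degree_exponent, degree_min = degree_min,
         degree_max = degree_max, ppi_edge_prob = ppi_edge_prob,
         label_slope = label_slope, label_intercept = label_intercept,
         seed = as.integer(seed)),
    class = "network_sim_config"
  )
}

# Draw n values from a discrete truncated power law p(k) ~ k^(-alpha).
.rtrunc_powerlaw <- function(n, alpha, kmin, kmax) {
  k <- kmin:kmax
  p <- k^(-alpha)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

#' Simulate bioactivity and PPI tables with a planted signature
#'
#' @param config A [network_sim_config()].
#' @return A list with `bioactivity` (compound_id, gene_symbol,
#'   endpoint_type, value), `ppi` (gene_a, gene_b, score; symmetric on
#'   ingest), `labels` (tibble compound_id, hit, connectivity) and
#'   `planted` (character vector of planted STG ids).
#' @export
simulate_constellation <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  set.seed(substream_seed(config$seed, 0L))

  drugs <- sprintf("CPD%05d", seq_len(config$n_drugs))
  eptg_pool <- sprintf("EPTG%04d", seq_len(config$n_eptg))
  stgs <- sprintf("STG%05d", seq_len(config$n_stg))
  planted <- if (config$n_planted_stg > 0) stgs[seq_len(config$n_planted_stg)] else character()

  # Drug -> ePTG annotations (every drug gets >= 1).
  deg <- .rtrunc_powerlaw(config$n_drugs, config$degree_exponent,
                          config$degree_min, config$degree_max)
  bio <- purrr::map2_dfr(drugs, deg, function(d, k) {
    genes <- sample(eptg_pool, min(k, config$n_eptg))
    tibble::tibble(
      compound_id = d, gene_symbol = genes,
      endpoint_type = sample(c("KI", "EC50", "IC50"), length(genes),
                             replace = TRUE, prob = c(0.4, 0.3, 0.3)),
      value = round(10^runif(length(genes), 0, 4), 2)
    )
  })
  ann <- dplyr::distinct(bio[, c("compound_id", "gene_symbol")])

  # Background PPI edges: Bernoulli(ppi_edge_prob) per (pool ePTG, STG)
  # pair, scores Uniform(0, 1).  Drawn sparsely.
  n_pairs <- as.double(config$n_eptg) * config$n_stg
  n_edges <- rbinom(1, min(n_pairs, .Machine$integer.max), config$ppi_edge_prob)
  idx <- sample.int(n_pairs, n_edges)
  bg <- tibble::tibble(
    gene_a = eptg_pool[((idx - 1) %% config$n_eptg) + 1],
    gene_b = stgs[((idx - 1) %/% config$n_eptg) + 1],
    score = runif(n_edges)
  )

  # Planted wiring: wire each planted STG to `planted_drugs_per_stg`
  # designated drugs through one of each drug's own ePTGs, covering
  # every designated drug at least once (round robin over a shuffled
  # designated set).
  pl <- tibble::tibble(gene_a = character(), gene_b = character(),
                       score = double())
  designated <- character()
  if (length(planted)) {
    designated <- sample(drugs, config$n_hits)
    n_wires <- config$n_planted_stg * config$planted_drugs_per_stg
    wire_drugs <- rep_len(sample(designated), n_wires)
    wire_stg <- rep(planted, each = config$planted_drugs_per_stg)
    gene_n_drugs <- table(ann$gene_symbol)
    wire_eptg <- vapply(wire_drugs, function(d) {
      genes <- ann$gene_symbol[ann$compound_id == d]
      # prefer an ePTG annotated by this drug alone, so the planted
      # path stays specific to the designated drug
      private <- genes[gene_n_drugs[genes] == 1]
      pick <- if (length(private)) private else genes
      pick[sample.int(length(pick), 1)]
    }, character(1))
    pl <- tibble::tibble(gene_a = unname(wire_eptg), gene_b = wire_stg,
                         score = runif(n_wires, 0.6, 1))
  }
  ppi <- dplyr::bind_rows(bg, pl)
  ppi <- dplyr::slice_max(dplyr::group_by(ppi, .data$gene_a, .data$gene_b),
                          .data$score, n = 1, with_ties = FALSE)
  ppi <- dplyr::arrange(dplyr::ungroup(ppi), .data$gene_a, .data$gene_b)

  # Integrated connectivity of each drug to the planted set: number of
  # distinct (ePTG of drug, planted STG) pairs with a kept edge.
  kept <- ppi[ppi$score >= 0.6 & ppi$gene_b %in% planted, ]
  paths <- dplyr::inner_join(ann, kept, by = c(gene_symbol = "gene_a"),
                             relationship = "many-to-many")
  k_planted <- dplyr::count(paths, .data$compound_id, name = "connectivity")
  labels <- tibble::tibble(compound_id = drugs) |>
    dplyr::left_join(k_planted, by = "compound_id") |>
    dplyr::mutate(connectivity = dplyr::coalesce(.data$connectivity, 0L))
  p_hit <- sigmoid(config$label_slope * labels$connectivity + config$label_intercept)
  labels$hit <- as.integer(runif(nrow(labels)) < p_hit)

  list(bioactivity = bio, ppi = ppi, labels = labels, planted = planted,
       designated = sort(designated))
}
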