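#' Built-in marker-defined population definitions
#'
#' The screening populations used for patient samples: glioblastoma
#' cells are (Nestin+ or S100B+) and CD45-; immune cells are CD45+ and
#' Nestin-/S100B-; `other` cells are triple-negative.  Cells matching no
#' definition (e.g. Nestin+CD45+) are labelled `"unassigned"` and stay
#' in the all-cells denominator.
#'
#' @param defs Named list of one-sided formulas over the boolean gate
#'   columns; order is the match priority.
#' @return The definition list, classed `population_defs`.
#' @export
population_defs <- function(defs = list(
                              glioblastoma = ~ (nestin | s100b) & !cd45,
                              immune = ~ cd45 & !nestin & !s100b,
                              other = ~ !nestin & !s100b & !cd45)) {
  stopifnot(is.list(defs), !is.null(names(defs)))
  structure(defs, class = "population_defs")
}

#' Assign each cell to a marker-defined population
#'
#' Evaluates each population definition over the gate columns; a cell
#' gets the first matching population, or `"unassigned"` if none match.
#' With `strict = TRUE`, a cell matching two definitions raises an error
#' instead of using definition order as priority.
#'
#' @param cells Gated cell-level table (boolean marker columns).
#' @param defs A [population_defs()] list.
#' @param strict Error on overlapping definitions instead of using
#'   definition order.
#' @return `cells` with a `population` column.
#' @export
classify_populations <- function(cells, defs = population_defs(), strict = FALSE) {
  cells <- tibble::as_tibble(cells)
  match_mat <- vapply(defs, function(f) {
    v <- rlang::eval_tidy(rlang::f_rhs(f), data = cells)
    if (!is.logical(v)) abort("population definitions must evaluate to booleans")
    v
  }, logical(nrow(cells)))
  if (nrow(cells) == 1) match_mat <- matrix(match_mat, nrow = 1,
                                            dimnames = list(NULL, names(defs)))
  n_match <- rowSums(match_mat)
  if (strict && any(n_match > 1)) {
    abort("overlapping population definitions match the same cell; set a priority order")
  }
  first <- apply(match_mat, 1, function(r) which(r)[1])
  cells$population <- ifelse(n_match == 0, "unassigned", names(defs)[first])
  cells
}

#' Per-well population fractions
#'
#' The denominator is every cell in the well (any DAPI+ nucleus in the
#' imaging assay), including unassigned cells.
#'
#' @param cells Classified cell table (needs `population` and the well
#'   metadata columns).
#' @param populations Population names to report fractions for; defaults
#'   to all present except `"unassigned"`.
#' @param exclude_apoptotic Drop cells flagged `apoptotic` before
#'   counting.
#' @return Tibble with one row per well x population: metadata columns,
#'   `n_cells`, `n_total`, `fraction`.
#' @export
population_fractions <- function(cells, populations = NULL,
                                 exclude_apoptotic = FALSE) {
  cells <- tibble::as_tibble(cells)
  if (exclude_apoptotic && "apoptotic" %in% names(cells)) {
    cells <- cells[!cells$apoptotic, ]
  }
  if (is.null(populations)) {
    populations <- setdiff(unique(cells$population), "unassigned")
  }
  meta_cols <- intersect(
    c("plate_id", "well_id", "patient_id", "drug_name", "concentration_um",
      "replicate"),
    names(cells))
  totals <- dplyr::count(cells, dplyr::across(dplyr::all_of(meta_cols)),
                         name = "n_total")
  if (any(totals$n_total < 1)) warn("empty wells excluded from fractions")
  counts <- dplyr::count(cells[cells$population %in% populations, ],
                         dplyr::across(dplyr::all_of(c(meta_cols, "population"))),
                         name = "n_cells")
  grid <- tidyr::expand_grid(totals, population = populations)
  dplyr::left_join(grid, counts, by = c(meta_cols, "population")) |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L),
                  fraction = .data$n_cells / .data$n_total)
}

#' PCY score from target-population fractions
#'
#' `pcy = 1 - tp_drug / tp_dmso`, the drug-induced relative reduction of
#' the target population: 1 is the strongest possible on-target
#' response, 0 means no effect or equal cytotoxicity, negative values
#' mean higher toxicity to the non-target populations.
#'
#' @param tp_drug,tp_dmso Target-population fractions (drug-averaged and
#'   DMSO-averaged); vectorised.
#' @return PCY scores; `NA` with a warning where `tp_dmso` is 0.
#' @export
compute_pcy_score <- function(tp_drug, tp_dmso) {
  if (any(tp_drug < 0, na.rm = TRUE) || any(tp_dmso < 0, na.rm = TRUE)) {
    abort("fractions must be non-negative")
  }
  undefined <- !is.na(tp_dmso) & tp_dmso == 0
  if (any(undefined)) warn("TP_DMSO = 0: PCY score undefined, returning NA")
  out <- 1 - tp_drug / tp_dmso
  out[undefined] <- NA_real_
  out
}

#' Two-sample t test of drug vs DMSO per-well fractions
#'
#' Welch t-test on per-well target-population fractions.  The one-tailed
#' alternative is a *reduction* under drug (drug fraction < DMSO
#' fraction), matching an on-target response.
#'
#' @param drug_fractions,dmso_fractions Per-well fractions.
#' @param tails `"one"` or `"two"`.
#' @return p-value in \[0, 1\]; `NA` with a warning when either group has
#'   fewer than 2 wells.
#' @export
test_drug_response <- function(drug_fractions, dmso_fractions,
                               tails = c("one", "two")) {
  tails <- match.arg(tails)
  drug_fractions <- drug_fractions[is.finite(drug_fractions)]
  dmso_fractions <- dmso_fractions[is.finite(dmso_fractions)]
  if (length(drug_fractions) < 2 || length(dmso_fractions) < 2) {
    warn("fewer than 2 wells in a group: p-value is NA")
    return(NA_real_)
  }
  if (sd(drug_fractions) == 0 && sd(dmso_fractions) == 0) {
    return(if (identical(mean(drug_fractions), mean(dmso_fractions)))
      (if (tails == "one") 0.5 else 1) else NA_real_)
  }
  alt <- if (tails == "one") "less" else "two.sided"
  t.test(drug_fractions, dmso_fractions, alternative = alt)$p.value
}

#' Multiple-testing adjustment with the screening convention
#'
#' `method = "auto"` uses Holm for families of fewer than 20 p-values
#' and Benjamini-Hochberg step-up FDR otherwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"auto"`, `"holm"` or `"bh"`.
#' @return Adjusted q-values.
#' @export
adjust_pvalues <- function(p, method = c("auto", "holm", "bh")) {
  method <- match.arg(method)
  keep <- !is.na(p)
  if (any(!is.finite(p[keep])) || any(p[keep] < 0) || any(p[keep] > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  if (method == "auto") method <- if (sum(keep) < 20) "holm" else "bh"
  p.adjust(p, method = if (method == "holm") "holm" else "BH")
}

#' Score drug responses on a classified cell table
#'
#' The full per-sample scoring chain: per-well target fractions, the
#' unweighted per-drug mean across replicate wells, PCY scores against
#' the DMSO mean, Welch t-tests on per-well fractions, multiple-testing
#' adjustment within each patient sample (all drugs x concentrations)
#' and sample-level hit calls.
#'
#' @param cells Gated + classified cell table (see
#'   [classify_populations()]); `drug_name == "DMSO"` marks control
#'   wells.
#' @param target Target population for the score.
#' @param tails Tails of the replicate t-test (see
#'   [test_drug_response()]).
#' @param adjust Multiple-testing method (see [adjust_pvalues()]).
#' @param exclude_apoptotic Drop apoptotic-flagged cells first.
#' @return Tibble with one row per patient x drug x concentration:
#'   `pcy_score`, `n_replicates`, `p_value`, `q_value`, `on_target_hit`.
#' @export
score_drug_responses <- function(cells, target = "glioblastoma",
                                 tails = c("one", "two"),
                                 adjust = c("auto", "holm", "bh"),
                                 exclude_apoptotic = FALSE) {
  tails <- match.arg(tails)
  adjust <- match.arg(adjust)
  fr <- population_fractions(cells, populations = target,
                             exclude_apoptotic = exclude_apoptotic)
  if (!"patient_id" %in% names(fr)) fr$patient_id <- "sample1"
  if (!"concentration_um" %in% names(fr)) fr$concentration_um <- NA_real_

  dmso <- fr[fr$drug_name == "DMSO", ]
  drugged <- fr[fr$drug_name != "DMSO", ]
  if (nrow(dmso) == 0) abort("no DMSO control wells found")

  res <- drugged |>
    dplyr::group_by(.data$patient_id, .data$drug_name, .data$concentration_um) |>
    dplyr::summarise(tp_drug = mean(.data$fraction),
                     n_replicates = dplyr::n(),
                     .wells = list(.data$fraction), .groups = "drop")
  dm <- dmso |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(tp_dmso = mean(.data$fraction),
                     .dmso_wells = list(.data$fraction), .groups = "drop")
  res <- dplyr::left_join(res, dm, by = "patient_id")
  res$pcy_score <- compute_pcy_score(res$tp_drug, res$tp_dmso)
  res$p_value <- purrr::map2_dbl(res$.wells, res$.dmso_wells,
                                 function(a, b) test_drug_response(a, b, tails))
  res <- res |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(q_value = adjust_pvalues(.data$p_value, adjust)) |>
    dplyr::ungroup() |>
    dplyr::select(-".wells", -".dmso_wells")
  call_hits(res, level = "sample")
}

#' Flag on-target hits
#'
#' Sample level: `pcy_score > 0` and `q_value < 0.05` (the volcano-plot
#' thresholds, `-log10(q) > 1.3`).  Cohort level: mean PCY score across
#' patients `> 0.03` flags a cohort-level top drug.
#'
#' @param responses Drug-response tibble (needs `pcy_score` plus
#'   `q_value` at sample level or `patient_id` at cohort level).
#' @param level `"sample"` or `"cohort"`.
#' @return At sample level, `responses` with an `on_target_hit` column
#'   (missing q-values are never hits).  At cohort level, one row per
#'   drug with `mean_pcy_score` and `cohort_hit`.
#' @export
call_hits <- function(responses, level = c("sample", "cohort")) {
  level <- match.arg(level)
  if (level == "sample") {
    responses$on_target_hit <- !is.na(responses$pcy_score) &
      !is.na(responses$q_value) &
      responses$pcy_score > 0 & responses$q_value < 0.05
    return(responses)
  }
  responses |>
    dplyr::group_by(.data$drug_name) |>
    dplyr::summarise(mean_pcy_score = mean(.data$pcy_score, na.rm = TRUE),
                     n_patients = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cohort_hit = .data$mean_pcy_score > 0.03)
}

#' Cell-line viability score
#'
#' For lines without a marker-defined target population, drug response
#' is the relative reduction of per-well totals: total cell number
#' (adherent lines) or 2D projected total spheroid area (spheroid
#' lines): `1 - mean(drug totals) / mean(DMSO totals)`.
#'
#' @param drug_totals,dmso_totals Per-well totals (counts or areas).
#' @return Viability score; `NA` when the DMSO mean is 0.
#' @export
viability_score <- function(drug_totals, dmso_totals) {
  m <- mean(dmso_totals)
  if (!is.finite(m) || m == 0) {
    warn("DMSO mean total is 0: viability score undefined")
    return(NA_real_)
  }
  1 - mean(drug_totals) / m
}
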