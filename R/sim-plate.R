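#' Configuration for a simulated drug screening plate
#'
#' Describes an ex vivo screening plate of dissociated tumour material:
#' every well receives a Poisson-distributed number of cells drawn from a
#' patient-specific baseline composition over the three marker-defined
#' populations (glioblastoma, immune, other).  Drug effects act as
#' per-population survival multipliers in \[0, 1\] applied to the expected
#' population counts before a multinomial redraw, which models the
#' *relative* reduction that the fraction-based PCY readout measures.
#'
#' @param n_patients Number of patient samples (one plate each).
#' @param n_drugs Number of distinct drugs per plate.
#' @param wells_per_drug Replicate wells per drug (screens used 3-4).
#' @param wells_dmso Number of DMSO vehicle-control wells per plate.
#' @param cells_per_well_mean Poisson mean of cells seeded per well.
#' @param baseline_composition Either a single probability vector over
#'   `c(glioblastoma, immune, other)` used for every patient, or a matrix
#'   with one row per patient.  Rows must sum to 1.
#' @param effect_map Tibble/data frame with columns `drug_name`,
#'   `population`, `survival` (in \[0, 1\]).  Populations absent for a drug
#'   default to survival 1.  `NULL` means no drug effects.
#' @param seed Integer master seed.
#' @return A list of class `plate_sim_config`.
#' @export
plate_sim_config <- function(n_patients = 1,
                             n_drugs = 1,
                             wells_per_drug = 4,
                             wells_dmso = 16,
                             cells_per_well_mean = 1000,
                             baseline_composition = c(glioblastoma = 0.3,
                                                      immune = 0.3,
                                                      other = 0.4),
                             effect_map = NULL,
                             seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  n_drugs <- check_count(n_drugs, "n_drugs")
  wells_per_drug <- check_count(wells_per_drug, "wells_per_drug")
  wells_dmso <- check_count(wells_dmso, "wells_dmso")
  cells_per_well_mean <- check_positive(cells_per_well_mean, "cells_per_well_mean")

  comp <- baseline_composition
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = n_patients, ncol = 3, byrow = TRUE)
  comp <- as.matrix(comp)
  if (ncol(comp) != 3 || nrow(comp) != n_patients) {
    abort("`baseline_composition` must have 3 columns (glioblastoma, immune, other) and one row per patient")
  }
  check_prob(comp, "baseline_composition")
  if (any(abs(rowSums(comp) - 1) > 1e-12)) {
    abort("`baseline_composition` rows must sum to 1 (tolerance 1e-12)")
  }
  colnames(comp) <- c("glioblastoma", "immune", "other")

  if (is.null(effect_map)) {
    effect_map <- tibble::tibble(drug_name = character(), population = character(),
                                 survival = double())
  }
  effect_map <- tibble::as_tibble(effect_map)
  stopifnot(all(c("drug_name", "population", "survival") %in% names(effect_map)))
  check_prob(effect_map$survival, "effect_map$survival")

  structure(
    list(n_patients = n_patients, n_drugs = n_drugs,
         wells_per_drug = wells_per_drug, wells_dmso = wells_dmso,
         cells_per_well_mean = cells_per_well_mean,
         baseline_composition = comp, effect_map = effect_map,
         seed = as.integer(seed)),
    class = "plate_sim_config"
  )
}

# Survival multipliers for one drug as a named length-3 vector.
.survival_vector <- function(effect_map, drug) {
  s <- c(glioblastoma = 1, immune = 1, other = 1)
  rows <- effect_map[effect_map$drug_name == drug, ]
  s[rows$population] <- rows$survival
  s
}

#' Closed-form expected PCY score under the plate simulation model
#'
#' With baseline composition `f` and survival multipliers `s`, the
#' expected post-drug fraction of population *p* is
#' `s_p f_p / sum_q(s_q f_q)` and the expected PCY score of the target
#' population is `1 - (expected drug fraction / f_target)`.
#'
#' @param composition Named probability vector over the three populations.
#' @param survival Named survival-multiplier vector (missing names = 1).
#' @param target Target population name.
#' @return Expected PCY score (a single number).
#' @export
expected_pcy_score <- function(composition, survival, target = "glioblastoma") {
  s <- c(glioblastoma = 1, immune = 1, other = 1)
  s[names(survival)] <- survival
  denom <- sum(s * composition[names(s)])
  if (denom <= 0) abort("empty wells expected: all populations have survival 0")
  drug_fraction <- s[target] * composition[target] / denom
  unname(1 - drug_fraction / composition[target])
}

#' Simulate cell-level well tables for a drug screening plate
#'
#' Generates one plate per patient with `wells_dmso` vehicle wells and
#' `wells_per_drug` replicate wells per drug.  Cell counts per well are
#' Poisson; the population of each cell is drawn from the post-effect
#' renormalised composition; boolean marker gates are consistent with the
#' population label (glioblastoma: Nestin+ or S100B+, CD45-; immune:
#' CD45+ only; other: triple-negative).  An `apoptotic` flag is drawn
#' independently of population at rate `apoptotic_rate`.
#'
#' @param config A [plate_sim_config()].
#' @param apoptotic_rate Probability that a cell is flagged apoptotic.
#' @return A list with `cells` (the cell-level table, one row per cell)
#'   and `truth` (tibble of closed-form expected PCY scores per patient,
#'   drug and population).
#' @export
simulate_plate <- function(config, apoptotic_rate = 0.05) {
  stopifnot(inherits(config, "plate_sim_config"))
  drugs <- if (config$n_drugs > 0) sprintf("drug%02d", seq_len(config$n_drugs)) else character()
  conditions <- c("DMSO", drugs)
  n_wells_cond <- c(config$wells_dmso, rep(config$wells_per_drug, length(drugs)))

  # Degenerate check: a population with probability 1 whose survival is 0
  # in some condition implies structurally empty wells.
  for (p in seq_len(config$n_patients)) {
    f <- config$baseline_composition[p, ]
    for (d in drugs) {
      s <- .survival_vector(config$effect_map, d)
      if (sum(s * f) <= 0) abort("empty wells expected: degenerate composition/effect combination")
    }
  }

  pops <- c("glioblastoma", "immune", "other")
  out <- vector("list", config$n_patients)
  truth <- vector("list", config$n_patients)
  well_idx <- 0L
  for (p in seq_len(config$n_patients)) {
    patient <- sprintf("P%03d", p)
    f <- config$baseline_composition[p, ]
    plate <- sprintf("%s_plate1", patient)
    rows <- vector("list", sum(n_wells_cond))
    r <- 0L
    for (ci in seq_along(conditions)) {
      drug <- conditions[ci]
      s <- if (drug == "DMSO") c(glioblastoma = 1, immune = 1, other = 1) else
        .survival_vector(config$effect_map, drug)
      probs <- s * f
      probs <- probs / sum(probs)
      for (w in seq_len(n_wells_cond[ci])) {
        well_idx <- well_idx + 1L
        set.seed(substream_seed(config$seed, well_idx))
        n <- rpois(1, config$cells_per_well_mean)
        if (n == 0) next
        counts <- as.integer(rmultinom(1, n, probs))
        pop <- rep(pops, counts)
        n_tot <- length(pop)
        nestin <- s100b <- cd45 <- logical(n_tot)
        is_gbm <- pop == "glioblastoma"
        # Glioblastoma cells: Nestin+ or S100B+ (at least one), CD45-.
        u1 <- runif(n_tot); u2 <- runif(n_tot)
        nestin[is_gbm] <- u1[is_gbm] < 0.75
        s100b[is_gbm] <- u2[is_gbm] < 0.6 | !nestin[is_gbm]
        cd45[pop == "immune"] <- TRUE
        rows[[r <- r + 1L]] <- tibble::tibble(
          plate_id = plate,
          well_id = sprintf("%s_w%03d", plate, well_idx),
          drug_name = drug,
          concentration_um = if (drug == "DMSO") 0 else 20,
          replicate = w,
          patient_id = patient,
          population_true = pop,
          nestin = nestin, s100b = s100b, cd45 = cd45,
          apoptotic = runif(n_tot) < apoptotic_rate
        )
      }
    }
    out[[p]] <- dplyr::bind_rows(rows)
    truth[[p]] <- purrr::map_dfr(drugs, function(d) {
      s <- .survival_vector(config$effect_map, d)
      tibble::tibble(
        patient_id = patient, drug_name = d, population = pops,
        expected_pcy = purrr::map_dbl(pops, function(tp)
          expected_pcy_score(f, s, target = tp))
      )
    })
  }
  cells <- dplyr::bind_rows(out)
  cells$cell_id <- sprintf("c%07d", seq_len(nrow(cells)))
  cells <- dplyr::relocate(cells, "cell_id")
  list(cells = cells, truth = dplyr::bind_rows(truth))
}
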