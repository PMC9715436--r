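# Aggregation of per-predictor outputs into the two ensemble scores:
# a Fermi-Dirac energy score ES and a summed probability score PS.

#' Thermodynamic constants for the energy score
#'
#' @param R gas constant in kcal mol^-1 K^-1 (default 1.987e-3)
#' @param T temperature in kelvin (default 310.15, i.e. 37 C)
#' @return list of class `thermo_constants` with `R`, `T` and `RT`
#' @export
thermo_constants <- function(R = 1.987e-3, T = 310.15) {
  if (R <= 0 || T <= 0) stop("R and T must be positive")
  structure(list(R = R, T = T, RT = R * T), class = "thermo_constants")
}

#' Fermi-Dirac energy score (ES)
#'
#' Aggregates predictor interaction energies as
#' \deqn{ES = \sum_i \frac{1}{1 + e^{E_i/(RT)}}}
#' Each term lies in (0, 1): a strongly negative (stable) duplex contributes
#' nearly 1, a zero energy ("no stable duplex") contributes exactly 0.5, and
#' ES is strictly decreasing in every E_i. An empty energy list gives 0.
#'
#' @param energies numeric vector of interaction energies E_i in kcal/mol
#' @param constants a [thermo_constants()] object
#' @return ES, a dimensionless score in [0, length(energies))
#' @export
energy_score <- function(energies, constants = thermo_constants()) {
  if (length(energies) == 0) return(0)
  if (any(!is.finite(energies))) stop("energies must be finite")
  sum(1 / (1 + exp(energies / constants$RT)))
}

#' Summed probability score (PS)
#'
#' The plain sum of per-predictor probability outputs; an empty list gives 0.
#'
#' @param scores numeric vector of probabilities SCORE_i in [0, 1]
#' @return PS, in [0, length(scores)]
#' @export
probability_score <- function(scores) {
  if (length(scores) == 0) return(0)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("probability scores must lie in [0, 1]")
  }
  sum(scores)
}

#' Build a classifier feature vector from an interaction candidate
#'
#' ES is computed from the candidate's energy-kind outputs and PS from its
#' probability-kind outputs; outputs with missing values (failed plugins) are
#' dropped from both. Optional raw per-predictor values are appended in fixed
#' predictor-id order as `raw_<id>` columns.
#'
#' @param candidate an `interaction_candidate` from [run_predictor_ensemble()]
#' @param constants a [thermo_constants()] object
#' @param include_raw append raw per-predictor values
#' @return one-row data.frame: `mirna_id`, `gene_symbol`, `species`, `ES`,
#'   `PS`, `n_energy`, `n_prob` (+ raw columns)
#' @export
build_feature_vector <- function(candidate, constants = thermo_constants(),
                                 include_raw = FALSE) {
  outs <- Filter(function(o) is.finite(o$value), candidate$outputs)
  if (length(outs) == 0) {
    stop(sprintf("candidate %s/%s has no usable predictor outputs",
                 candidate$mirna_id, candidate$gene_symbol))
  }
  kinds <- vapply(outs, `[[`, "", "kind")
  values <- vapply(outs, `[[`, 0, "value")
  fv <- data.frame(
    mirna_id = candidate$mirna_id, gene_symbol = candidate$gene_symbol,
    species = candidate$species,
    ES = energy_score(values[kinds == "energy"], constants),
    PS = probability_score(values[kinds == "probability"]),
    n_energy = sum(kinds == "energy"), n_prob = sum(kinds == "probability"),
    stringsAsFactors = FALSE)
  if (include_raw) {
    ord <- order(vapply(outs, `[[`, "", "predictor_id"))
    for (o in outs[ord]) fv[[paste0("raw_", o$predictor_id)]] <- o$value
  }
  fv
}

#' Feature matrix for all miRNA x transcript pairs
#'
#' Runs the predictor ensemble on every pair and stacks the feature vectors.
#'
#' @param mirnas data.frame of miRNAs (`id`, `sequence`)
#' @param transcripts data.frame of transcript regions (`gene_symbol`,
#'   `sequence`, `species`)
#' @param specs list of [predictor_spec()]
#' @param constants a [thermo_constants()] object
#' @param pairs optional data.frame (`mirna_id`, `gene_symbol`) restricting
#'   which pairs are evaluated
#' @param include_raw append raw per-predictor values
#' @return data.frame of feature vectors, one row per pair
#' @export
build_feature_matrix <- function(mirnas, transcripts,
                                 specs = default_predictor_specs(),
                                 constants = thermo_constants(),
                                 pairs = NULL, include_raw = FALSE) {
  if (is.null(pairs)) {
    pairs <- expand.grid(mirna_id = mirnas$id,
                         gene_symbol = transcripts$gene_symbol,
                         stringsAsFactors = FALSE)
  }
  mi <- match(pairs$mirna_id, mirnas$id)
  ti <- match(pairs$gene_symbol, transcripts$gene_symbol)
  if (anyNA(mi) || anyNA(ti)) stop("pairs reference unknown miRNA or gene ids")
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    cand <- run_predictor_ensemble(as.list(mirnas[mi[k], ]),
                                   as.list(transcripts[ti[k], ]), specs)
    build_feature_vector(cand, constants, include_raw)
  })
  do.call(rbind, rows)
}
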