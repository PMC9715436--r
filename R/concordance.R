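# Prediction-expression concordance: overlap of predicted targets with
# expression-modulated genes, an upper-tail hypergeometric enrichment
# diagnostic, and direction consistency (miRNA targeting predicts
# downregulation).

#' Overlap between predicted targets and modulated genes
#'
#' "Modulated" means fold-change class != unchanged under the panel
#' thresholds. The overlap is tested for enrichment with a one-sided
#' upper-tail hypergeometric test: the probability of drawing at least the
#' observed overlap when `n_predicted` genes are drawn from a panel of
#' `n_panel` containing `n_modulated` modulated genes. The p-value is an
#' added diagnostic; the counts are the primary result.
#'
#' @param predictions data.frame of target predictions
#'   ([predict_interaction()])
#' @param records data.frame of fold-change records ([delta_delta_ct()])
#' @param panel manifest data.frame ([read_panel_manifest()])
#' @return list of class `concordance_result`: `n_panel`, `n_modulated`,
#'   `n_predicted`, `n_overlap`, `overlap_genes`, `p_value`, plus the
#'   direction fields of [direction_consistency()]
#' @export
prediction_expression_overlap <- function(predictions, records, panel) {
  panel_genes <- toupper(panel$gene_symbol)
  pred_genes <- unique(toupper(predictions$gene_symbol[predictions$predicted_target]))
  mod_records <- records[records$class != "unchanged", , drop = FALSE]
  mod_genes <- unique(toupper(mod_records$id))
  offenders <- setdiff(union(unique(toupper(predictions$gene_symbol)),
                             unique(toupper(records$id))), panel_genes)
  if (length(offenders)) {
    stop("gene symbol(s) outside the panel: ", paste(offenders, collapse = ", "))
  }
  overlap <- sort(intersect(pred_genes, mod_genes))
  k <- length(overlap)
  p <- phyper(k - 1, length(mod_genes),
              length(panel_genes) - length(mod_genes),
              length(pred_genes), lower.tail = FALSE)
  direction <- direction_consistency(predictions, records)
  structure(c(list(n_panel = length(panel_genes),
                   n_modulated = length(mod_genes),
                   n_predicted = length(pred_genes),
                   n_overlap = k, overlap_genes = overlap, p_value = p),
              direction),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance: %d of %d modulated genes among %d predicted targets (panel %d); hypergeometric p = %.3g\n",
              x$n_overlap, x$n_modulated, x$n_predicted, x$n_panel, x$p_value))
  cat(sprintf("  direction: %d down, %d up; consistency %.4f\n",
              x$n_predicted_down, x$n_predicted_up, x$consistency))
  invisible(x)
}

#' Direction consistency of predicted targets
#'
#' Counts predicted target genes falling in the down/up fold-change classes;
#' consistency = n_down / (n_down + n_up) since miRNA targeting predicts
#' downregulation. Predicted targets without an expression record are
#' excluded with a warning.
#'
#' @inheritParams prediction_expression_overlap
#' @return list: `n_predicted_down`, `n_predicted_up`, `consistency`
#'   (NaN when no predicted target is modulated)
#' @export
direction_consistency <- function(predictions, records) {
  pred_genes <- unique(toupper(predictions$gene_symbol[predictions$predicted_target]))
  rec_ids <- toupper(records$id)
  missing <- setdiff(pred_genes, rec_ids)
  if (length(missing)) {
    warning("predicted target(s) without an expression record, excluded: ",
            paste(missing, collapse = ", "))
    pred_genes <- setdiff(pred_genes, missing)
  }
  cls <- records$class[match(pred_genes, rec_ids)]
  n_down <- sum(cls == "down")
  n_up <- sum(cls == "up")
  list(n_predicted_down = n_down, n_predicted_up = n_up,
       consistency = if (n_down + n_up > 0) n_down / (n_down + n_up) else NaN)
}

#' Exhaustive hypergeometric tail probability (reference implementation)
#'
#' Enumerates every size-`n_drawn` subset of a panel of `n_panel` genes and
#' counts those overlapping a fixed `n_success` set in at least `k` genes.
#' Feasible for panels of size <= 12; used as an independent check of the
#' hypergeometric tail used by [prediction_expression_overlap()].
#'
#' @param k minimum overlap
#' @param n_success number of "success" genes in the panel
#' @param n_panel panel size
#' @param n_drawn number of genes drawn
#' @return P(X >= k) by enumeration
#' @export
hypergeom_tail_exhaustive <- function(k, n_success, n_panel, n_drawn) {
  stopifnot(n_panel <= 20, n_success <= n_panel, n_drawn <= n_panel)
  if (n_drawn == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(n_panel, n_drawn)
  hits <- colSums(subsets <= n_success)  # successes are genes 1..n_success
  mean(hits >= k)
}
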