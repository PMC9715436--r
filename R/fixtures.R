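# Bundled example data: the 17-member mature miRNA pool (published ids with
# synthetic stand-in sequences) and the reported cross-species prediction
# table used by the consistency and concordance examples.

#' The mature plant miRNA pool (synthetic stand-in sequences)
#'
#' Seventeen conserved plant miRNA family members as reported for the
#' *Moringa oleifera* seed-extract pool. The published work names the pool
#' members but not their sequences, so the bundled FASTA carries synthetic
#' 21-nt stand-in sequences under the real identifiers; only the ids and the
#' pool size should be treated as real.
#'
#' @return data.frame as from [read_mirna_fasta()]
#' @export
mol_mir_pool <- function() {
  read_mirna_fasta(system.file("extdata", "mol_mir_pool_synthetic.fa",
                               package = "mircross"))
}

#' Reported cross-species target predictions
#'
#' The reported per-pair class probabilities for the 19 adipogenesis-panel
#' genes predicted as plant-miRNA targets in both human and mouse, loaded as
#' two prediction tables in the format of [predict_interaction()] (strict
#' 0.60 cutoff).
#'
#' @param cutoff probability cutoff applied to the reported probabilities
#' @return list with elements `human` and `mouse`, each a prediction
#'   data.frame
#' @export
cross_species_prediction_table <- function(cutoff = 0.60) {
  df <- read.delim(system.file("extdata", "cross_species_predictions.tsv",
                               package = "mircross"),
                   sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
  split_df <- split(df, df$species)
  lapply(split_df, function(d) {
    data.frame(mirna_id = d$mirna_id, gene_symbol = toupper(d$gene_symbol),
               species = d$species, probability = d$probability,
               predicted_target = d$probability > cutoff, cutoff = cutoff,
               stringsAsFactors = FALSE)
  })
}
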