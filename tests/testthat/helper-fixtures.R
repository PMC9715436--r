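# Shared fixture builders: tiny FASTA/Ct fixtures are written to tempfiles at
# test time, feature-space clusters avoid the full sequence pipeline where
# the classifier itself is under test.

random_rna_string <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

write_fasta_lines <- function(entries, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}

# Gaussian (ES, PS) clusters with a controlled mean separation between the
# classes; used for classifier-level properties.
make_feature_clusters <- function(n_per_class, delta_es = 2, delta_ps = 1,
                                  sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    neg <- data.frame(ES = rnorm(n_per_class, 1.0, sd),
                      PS = rnorm(n_per_class, 0.5, sd))
    pos <- data.frame(ES = rnorm(n_per_class, 1.0 + delta_es, sd),
                      PS = rnorm(n_per_class, 0.5 + delta_ps, sd))
    neg$label <- "negative"; pos$label <- "positive"
    df <- rbind(neg, pos)
    df$mirna_id <- sprintf("m%03d", seq_len(nrow(df)))
    df$gene_symbol <- sprintf("G%03d", seq_len(nrow(df)))
    df
  })
}

# Minimal Ct table: one housekeeper row per sample plus target rows, built
# from a named list group -> list(sample -> c(hk, targets...)).
make_ct_table <- function(groups) {
  rows <- list()
  for (g in names(groups)) {
    for (s in names(groups[[g]])) {
      vals <- groups[[g]][[s]]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, group = g, target_id = names(vals),
        ct = unname(vals),
        is_housekeeping = names(vals) == "HK", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
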