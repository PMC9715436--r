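test_that("configurations are validated", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(mirna_length = 0), ">= 1")
  expect_error(synth_config(site_quality = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(utr_length = c(10, 5)), "utr_length")
  expect_error(synth_config(sites_per_target = 99), "exceed")
  expect_error(synth_config(groups = "only-one"), "2 groups")
})

test_that("generators are pure functions of their configuration", {
  cfg <- synth_config(seed = 42, n_genes = 12, n_pos = 8, n_neg = 8,
                      fraction_targeted = 0.5, sites_per_target = 2)
  d1 <- tempfile(); d2 <- tempfile()
  write_synth_dataset(cfg, d1)
  write_synth_dataset(cfg, d2)
  for (f in c("mirnas.fa", "panel.fa", "manifest.tsv", "labeled.tsv",
              "ct.csv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # changing the seed changes the data
  write_synth_dataset(synth_config(seed = 43, n_genes = 12, n_pos = 8,
                                   n_neg = 8, fraction_targeted = 0.5,
                                   sites_per_target = 2),
                      d2)
  expect_false(identical(readLines(file.path(d1, "mirnas.fa")),
                         readLines(file.path(d2, "mirnas.fa"))))
})

test_that("miRNA generation respects the pool geometry", {
  g <- gen_mirnas(synth_config(seed = 1, n_mirnas = 17, mirna_length = 21))
  expect_equal(nrow(g$mirnas), 17)
  expect_true(all(g$mirnas$length == 21))
  expect_true(all(grepl("^[ACGU]+$", g$mirnas$sequence)))
})

test_that("planted sites are where the ground truth says they are", {
  cfg <- synth_config(seed = 5, n_genes = 20, fraction_targeted = 0.5,
                      sites_per_target = 3, site_quality = 1.0)
  mi <- gen_mirnas(cfg)
  pa <- gen_transcript_panel_with_sites(cfg, mi$mirnas)
  truth <- pa$ground_truth$pairs
  expect_gt(nrow(truth), 0)
  for (i in seq_len(nrow(truth))) {
    tx <- pa$transcripts$sequence[pa$transcripts$gene_symbol ==
                                    truth$gene_symbol[i]]
    window <- substr(tx, truth$start[i] + 1, truth$end[i])
    m <- mi$mirnas$sequence[mi$mirnas$id == truth$mirna_id[i]]
    expect_identical(window, rna_reverse_complement(m))
  }
})

test_that("an untargeted panel has no planted pairs", {
  cfg <- synth_config(seed = 6, n_genes = 10, fraction_targeted = 0)
  mi <- gen_mirnas(cfg)
  pa <- gen_transcript_panel_with_sites(cfg, mi$mirnas)
  expect_equal(nrow(pa$ground_truth$pairs), 0)
})

test_that("planted pairs bind more strongly than non-planted pairs", {
  cfg <- synth_config(seed = 9, n_genes = 20, fraction_targeted = 0.5,
                      sites_per_target = 3)
  mi <- gen_mirnas(cfg)
  pa <- gen_transcript_panel_with_sites(cfg, mi$mirnas)
  truth <- pa$ground_truth$pairs
  spec <- predictor_spec("dup", "duplex")
  e_of <- function(mid, g) {
    scan_transcript(mi$mirnas[mi$mirnas$id == mid, ],
                    pa$transcripts[pa$transcripts$gene_symbol == g, ],
                    spec)$value
  }
  planted_e <- mapply(e_of, truth$mirna_id, truth$gene_symbol)
  withr::with_seed(10, {
    nonp <- expand.grid(mirna_id = mi$mirnas$id,
                        gene_symbol = pa$transcripts$gene_symbol,
                        stringsAsFactors = FALSE)
    nonp <- nonp[!paste(nonp$mirna_id, nonp$gene_symbol) %in%
                   paste(truth$mirna_id, truth$gene_symbol), ]
    nonp <- nonp[sample(nrow(nonp), 30), ]
  })
  random_e <- mapply(e_of, nonp$mirna_id, nonp$gene_symbol)
  expect_lt(mean(planted_e), mean(random_e))
})

test_that("labeled sets are balanced and more separated at high site quality", {
  base <- list(seed = 7, n_genes = 30, n_pos = 60, n_neg = 60,
               fraction_targeted = 0.5, sites_per_target = 4)
  lab_of <- function(q) {
    cfg <- do.call(synth_config, c(base, list(site_quality = q)))
    mi <- gen_mirnas(cfg)
    pa <- gen_transcript_panel_with_sites(cfg, mi$mirnas)
    gen_labeled_interactions(cfg, mi$mirnas, pa$transcripts, pa$ground_truth)
  }
  hi <- lab_of(1.0)
  expect_equal(as.vector(table(hi$label)), c(60, 60))
  sep <- function(lab) {
    m <- tapply(lab$ES, lab$label, mean)
    m[["positive"]] - m[["negative"]]
  }
  expect_gt(sep(hi), sep(lab_of(0.3)))
})

test_that("labeled-set generation demands enough planted pairs", {
  cfg <- synth_config(seed = 8, n_genes = 10, n_pos = 500, n_neg = 10,
                      fraction_targeted = 0.2, sites_per_target = 2)
  mi <- gen_mirnas(cfg)
  pa <- gen_transcript_panel_with_sites(cfg, mi$mirnas)
  expect_error(
    gen_labeled_interactions(cfg, mi$mirnas, pa$transcripts,
                             pa$ground_truth),
    "planted pairs")
})

test_that("noiseless Ct tables recover planted fold changes exactly", {
  cfg <- synth_config(seed = 12, n_genes = 15, noise_sd = 0)
  g <- gen_ct_table(cfg)
  rec <- delta_delta_ct(g$table, "ND", "HFD")
  truth <- g$ground_truth$log2fc[rec$id, "HFD"]
  expect_equal(-rec$ddct, unname(truth), tolerance = 1e-12)
  expect_equal(rec$fold_change, unname(2^truth), tolerance = 1e-12)
})

test_that("noisy Ct tables recover planted fold changes approximately", {
  cfg <- synth_config(seed = 13, n_genes = 40, replicates = 6,
                      noise_sd = 0.1)
  g <- gen_ct_table(cfg)
  rec <- delta_delta_ct(g$table, "ND", "HFD")
  truth <- g$ground_truth$log2fc[rec$id, "HFD"]
  expect_gte(mean(abs(-rec$ddct - truth) <= 0.15), 0.95)
})
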