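# Generators for every input the pipeline consumes: miRNA pools, transcript
# panels with planted binding sites of controlled quality, labeled
# interaction sets with features computed by the real pipeline, and Ct tables
# with planted group effects. Each generator draws from its own RNG stream
# derived from the master seed by a fixed label, and emits ground truth
# alongside the data.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions: a pool of 17 mature plant miRNAs of
#' 21 nt, an 84-gene expression panel, two diet groups with 3 replicates, and
#' perfect-complement planted sites (`site_quality = 1`) against uniformly
#' random negatives with 400 examples per class.
#'
#' @param seed master seed; every generator derives its own stream from it
#' @param n_mirnas number of miRNAs in the pool
#' @param mirna_length mature miRNA length (nt)
#' @param n_genes panel size
#' @param utr_length c(min, max) transcript length bounds (uniform)
#' @param fraction_targeted fraction of panel genes receiving planted sites
#' @param sites_per_target number of distinct miRNAs planted per targeted
#'   gene
#' @param site_quality fraction of planted-site positions left complementary
#'   (seed region degraded last)
#' @param n_pos,n_neg labeled-set class sizes
#' @param groups group labels; the first is the reference
#' @param replicates samples per group
#' @param log2fc_range uniform bounds for planted per-gene log2 fold changes
#' @param noise_sd Gaussian Ct noise SD (cycles)
#' @param ct_baseline housekeeper mean Ct
#' @param housekeeper housekeeping target id in generated Ct tables
#' @return list of class `synth_config`
#' @export
synth_config <- function(seed = 42L, n_mirnas = 17L, mirna_length = 21L,
                         n_genes = 84L, utr_length = c(300L, 800L),
                         fraction_targeted = 0.6, sites_per_target = 8L,
                         site_quality = 1.0, n_pos = 400L, n_neg = 400L,
                         groups = c("ND", "HFD"), replicates = 3L,
                         log2fc_range = c(-2, 2), noise_sd = 0.1,
                         ct_baseline = 20, housekeeper = "5S") {
  cfg <- list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
              mirna_length = as.integer(mirna_length),
              n_genes = as.integer(n_genes),
              utr_length = as.integer(utr_length),
              fraction_targeted = fraction_targeted,
              sites_per_target = as.integer(sites_per_target),
              site_quality = site_quality, n_pos = as.integer(n_pos),
              n_neg = as.integer(n_neg), groups = groups,
              replicates = as.integer(replicates),
              log2fc_range = log2fc_range, noise_sd = noise_sd,
              ct_baseline = ct_baseline, housekeeper = housekeeper)
  with(cfg, {
    if (n_mirnas < 1 || mirna_length < 1 || n_genes < 1 || replicates < 1) {
      stop("counts and lengths must be >= 1")
    }
    if (fraction_targeted < 0 || fraction_targeted > 1 ||
        site_quality < 0 || site_quality > 1) {
      stop("fractions must lie in [0, 1]")
    }
    if (noise_sd < 0) stop("noise SD must be >= 0")
    if (length(utr_length) != 2 || utr_length[1] > utr_length[2] ||
        utr_length[1] < mirna_length) {
      stop("utr_length must be c(min, max) with min >= mirna_length")
    }
    if (sites_per_target > n_mirnas) {
      stop("sites_per_target cannot exceed n_mirnas")
    }
    if (length(groups) < 2) stop("at least 2 groups are required")
  })
  structure(cfg, class = "synth_config")
}

random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic miRNA pool
#'
#' @param config a [synth_config()]
#' @return list: `mirnas` (data.frame id/sequence/length/species),
#'   `ground_truth` (generator provenance)
#' @export
gen_mirnas <- function(config) {
  withr::with_seed(substream_seed(config$seed, "mirnas"), {
    seqs <- vapply(seq_len(config$n_mirnas), function(i)
      random_rna(config$mirna_length), "")
  })
  mirnas <- data.frame(
    id = sprintf("syn-miR-%03d", seq_len(config$n_mirnas)),
    sequence = seqs, length = nchar(seqs), species = "synthetic",
    stringsAsFactors = FALSE)
  list(mirnas = mirnas,
       ground_truth = list(generator = "gen_mirnas", seed = config$seed))
}

# Degrade a perfect-complement site to the requested quality: mutate a random
# subset of positions to bases that can pair neither Watson-Crick nor G:U
# with the miRNA, choosing non-seed positions first so the seed is the last
# region to lose complementarity.
degrade_site <- function(site, mirna_seq, quality, seed_span = c(2L, 8L)) {
  L <- nchar(site)
  n_mut <- round((1 - quality) * L)
  if (n_mut == 0) return(site)
  # miRNA position k pairs sense-site position L - k + 1
  seed_site_pos <- L - seed_span[2]:seed_span[1] + 1
  non_seed <- setdiff(seq_len(L), seed_site_pos)
  order_pos <- c(sample(non_seed, length(non_seed)),
                 sample(seed_site_pos, length(seed_site_pos)))
  mut_pos <- order_pos[seq_len(n_mut)]
  s <- strsplit(site, "", fixed = TRUE)[[1]]
  m <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  forbidden <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
  for (p in mut_pos) {
    mb <- m[L - p + 1]
    choices <- setdiff(RNA_BASES, c(forbidden[[mb]], s[p]))
    s[p] <- choices[sample.int(length(choices), 1)]
  }
  paste(s, collapse = "")
}

#' Generate a transcript panel with planted binding sites
#'
#' Creates `n_genes` random transcripts; a `fraction_targeted` subset each
#' receives one planted site per assigned miRNA: the reverse complement of
#' the miRNA degraded to `site_quality`, at a recorded, non-overlapping
#' position. Ground truth lists every planted pair and site.
#'
#' @param config a [synth_config()]
#' @param mirnas miRNA data.frame from [gen_mirnas()]
#' @return list: `transcripts` (data.frame), `manifest` (panel manifest
#'   data.frame), `ground_truth` (list with `pairs` data.frame:
#'   mirna_id/gene_symbol/start/end)
#' @export
gen_transcript_panel_with_sites <- function(config, mirnas) {
  if (nrow(mirnas) == 0) stop("miRNA set must be non-empty")
  L_site <- config$mirna_length
  n_target <- round(config$fraction_targeted * config$n_genes)
  res <- withr::with_seed(substream_seed(config$seed, "panel"), {
    genes <- sprintf("GENE%03d", seq_len(config$n_genes))
    targeted <- if (n_target > 0) sample(genes, n_target) else character(0)
    pairs <- list(); seqs <- character(config$n_genes)
    for (gi in seq_len(config$n_genes)) {
      g <- genes[gi]
      assigned <- if (g %in% targeted) {
        mirnas[sample(nrow(mirnas), config$sites_per_target), , drop = FALSE]
      } else mirnas[0, , drop = FALSE]
      need <- nrow(assigned) * L_site
      for (attempt in 1:50) {
        len <- sample(config$utr_length[1]:config$utr_length[2], 1)
        if (len < max(need, L_site)) next
        tx <- strsplit(random_rna(len), "", fixed = TRUE)[[1]]
        # place non-overlapping sites by rejection
        starts <- integer(0); ok <- TRUE
        if (nrow(assigned) > 0) {
          for (k in seq_len(nrow(assigned))) {
            placed <- FALSE
            for (try in 1:200) {
              s0 <- sample.int(len - L_site + 1, 1) - 1L  # 0-based
              if (!any(s0 < starts + L_site & s0 + L_site > starts)) {
                starts <- c(starts, s0); placed <- TRUE; break
              }
            }
            if (!placed) { ok <- FALSE; break }
          }
        }
        if (!ok) next
        if (nrow(assigned) > 0) {
          for (k in seq_len(nrow(assigned))) {
            site <- degrade_site(rna_reverse_complement(assigned$sequence[k]),
                                 assigned$sequence[k], config$site_quality)
            tx[(starts[k] + 1):(starts[k] + L_site)] <-
              strsplit(site, "", fixed = TRUE)[[1]]
            pairs[[length(pairs) + 1]] <- data.frame(
              mirna_id = assigned$id[k], gene_symbol = g,
              start = starts[k], end = starts[k] + L_site,
              stringsAsFactors = FALSE)
          }
        }
        seqs[gi] <- paste(tx, collapse = "")
        break
      }
      if (!nzchar(seqs[gi])) {
        stop("could not place planted sites in gene ", g,
             " after bounded retries; increase utr_length")
      }
    }
    list(genes = genes, seqs = seqs, pairs = pairs)
  })
  transcripts <- data.frame(gene_symbol = res$genes, species = "synthetic",
                            region_kind = "3UTR", sequence = res$seqs,
                            length = nchar(res$seqs), stringsAsFactors = FALSE)
  manifest <- data.frame(gene_symbol = res$genes, pathway = "synthetic",
                         stringsAsFactors = FALSE)
  attr(manifest, "panel_name") <- "synthetic-panel"
  pairs <- if (length(res$pairs)) do.call(rbind, res$pairs) else
    data.frame(mirna_id = character(0), gene_symbol = character(0),
               start = integer(0), end = integer(0))
  list(transcripts = transcripts, manifest = manifest,
       ground_truth = list(generator = "gen_transcript_panel_with_sites",
                           seed = config$seed, pairs = pairs))
}

#' Generate a labeled interaction set with real pipeline features
#'
#' Positives are planted miRNA/gene pairs; negatives are sampled uniformly
#' from the non-planted pairs. Features (ES, PS) are computed by running the
#' actual predictor ensemble, never simulated.
#'
#' @param config a [synth_config()]
#' @param mirnas miRNA data.frame
#' @param transcripts transcript data.frame
#' @param ground_truth ground truth from [gen_transcript_panel_with_sites()]
#' @param specs predictor specs for feature computation
#' @param constants a [thermo_constants()]
#' @return data.frame of labeled feature vectors (`label` column:
#'   positive/negative)
#' @export
gen_labeled_interactions <- function(config, mirnas, transcripts,
                                     ground_truth,
                                     specs = default_predictor_specs(),
                                     constants = thermo_constants()) {
  planted <- ground_truth$pairs
  if (config$n_pos < 1) stop("n_pos must be >= 1")
  if (nrow(planted) < config$n_pos) {
    stop(sprintf("only %d planted pairs available for %d requested positives; increase fraction_targeted, sites_per_target or n_genes",
                 nrow(planted), config$n_pos))
  }
  all_pairs <- expand.grid(mirna_id = mirnas$id,
                           gene_symbol = transcripts$gene_symbol,
                           stringsAsFactors = FALSE)
  key <- function(df) paste(df$mirna_id, df$gene_symbol)
  non_planted <- all_pairs[!key(all_pairs) %in% key(planted), , drop = FALSE]
  if (nrow(non_planted) < config$n_neg) {
    stop("insufficient non-planted pairs for the requested negatives; use a larger panel")
  }
  sel <- withr::with_seed(substream_seed(config$seed, "labeled"), {
    list(pos = planted[sample(nrow(planted), config$n_pos), , drop = FALSE],
         neg = non_planted[sample(nrow(non_planted), config$n_neg), ,
                           drop = FALSE])
  })
  pos_fv <- build_feature_matrix(mirnas, transcripts, specs, constants,
                                 pairs = sel$pos[, c("mirna_id", "gene_symbol")])
  neg_fv <- build_feature_matrix(mirnas, transcripts, specs, constants,
                                 pairs = sel$neg)
  pos_fv$label <- "positive"
  neg_fv$label <- "negative"
  rbind(pos_fv, neg_fv)
}

#' Generate a Ct table with planted group effects
#'
#' Every sample gets a housekeeper well Ct ~ Normal(baseline, noise SD); each
#' target well Ct is the sample's housekeeper value plus a fixed per-gene
#' offset, minus the planted log2 fold change in non-reference groups, plus
#' independent Normal(0, noise SD) well noise. Ground truth stores the
#' planted per-gene log2 fold changes per non-reference group.
#'
#' @param config a [synth_config()]
#' @param target_ids optional target ids (default `GENE001..`)
#' @return list: `table` (Ct data.frame), `ground_truth` (list with `log2fc`
#'   matrix genes x non-reference groups and `offsets`)
#' @export
gen_ct_table <- function(config, target_ids = NULL) {
  if (config$replicates < 2) stop("at least 2 replicates per group are required")
  if (is.null(target_ids)) {
    target_ids <- sprintf("GENE%03d", seq_len(config$n_genes))
  }
  ref <- config$groups[1]
  alt <- setdiff(config$groups, ref)
  res <- withr::with_seed(substream_seed(config$seed, "ct"), {
    offsets <- runif(length(target_ids), 0, 10)
    fc <- matrix(runif(length(target_ids) * length(alt),
                       config$log2fc_range[1], config$log2fc_range[2]),
                 nrow = length(target_ids),
                 dimnames = list(target_ids, alt))
    rows <- list()
    for (g in config$groups) {
      for (r in seq_len(config$replicates)) {
        sid <- sprintf("%s_rep%d", g, r)
        hk_ct <- rnorm(1, config$ct_baseline, config$noise_sd)
        eff <- if (g == ref) 0 else fc[, g]
        ct <- hk_ct + offsets - eff +
          rnorm(length(target_ids), 0, config$noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, group = g,
          target_id = c(config$housekeeper, target_ids),
          ct = c(hk_ct, ct),
          is_housekeeping = c(TRUE, rep(FALSE, length(target_ids))),
          stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows), offsets = offsets, fc = fc)
  })
  list(table = res$table,
       ground_truth = list(generator = "gen_ct_table", seed = config$seed,
                           log2fc = res$fc, offsets = res$offsets))
}

#' Write a full synthetic dataset to disk
#'
#' Emits `mirnas.fa`, `panel.fa`, `manifest.tsv`, `labeled.tsv`, `ct.csv`
#' and `ground_truth.json` into a directory. Byte-identical for a given
#' configuration.
#'
#' @param config a [synth_config()]
#' @param dir output directory (created if needed)
#' @param with_labeled also compute and write the labeled interaction set
#'   (the slow step)
#' @return invisible list of the generated objects
#' @export
write_synth_dataset <- function(config, dir, with_labeled = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mi <- gen_mirnas(config)
  pa <- gen_transcript_panel_with_sites(config, mi$mirnas)
  ct <- gen_ct_table(config)
  write_mirna_fasta(mi$mirnas, file.path(dir, "mirnas.fa"))
  write_transcript_fasta(pa$transcripts, file.path(dir, "panel.fa"))
  write.table(pa$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(ct$table, file.path(dir, "ct.csv"), row.names = FALSE,
            quote = FALSE)
  labeled <- NULL
  if (with_labeled) {
    labeled <- gen_labeled_interactions(config, mi$mirnas, pa$transcripts,
                                        pa$ground_truth)
    write.table(labeled, file.path(dir, "labeled.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  truth <- list(config = unclass(config),
                planted_pairs = pa$ground_truth$pairs,
                ct_log2fc = as.data.frame(ct$ground_truth$log2fc))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(mirnas = mi, panel = pa, ct = ct, labeled = labeled))
}
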