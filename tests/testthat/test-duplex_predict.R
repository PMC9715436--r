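test_that("seed complementarity scores match hand enumeration", {
  mirna <- "UGACAGAAGAGAGUGAGCACA"
  perfect <- rna_reverse_complement(mirna)
  out <- seed_complementarity_score(mirna, paste0("AAAA", perfect, "GGGG"))
  expect_equal(out$value, 1.0)
  expect_equal(out$kind, "probability")

  # poly-A miRNA can only pair with U; a U-free site scores 0 at every offset
  polyA <- strrep("A", 21)
  expect_equal(seed_complementarity_score(polyA, strrep("C", 40))$value, 0)

  # 6 WC + 1 GU in the seed: replace the site base pairing miRNA position 5
  # (a C, pairing G) with U, which forms a G:U wobble
  mirna2 <- "AAGGGGGAAAAAAAAAAAAAA"   # seed (pos 2-8) = A G G G G G A
  site <- rna_reverse_complement(mirna2)
  L <- nchar(site)
  pos <- L - 5 + 1  # site position pairing miRNA position 5 (a G -> C)
  substr(site, pos, pos) <- "U"
  out2 <- seed_complementarity_score(mirna2, site, wobble_weight = 0.5)
  expect_equal(out2$value, (6 + 0.5) / 7)

  expect_error(seed_complementarity_score(mirna, "ACGU"), "shorter")
})

test_that("seed score is monotone in the wobble weight", {
  withr::with_seed(21, {
    for (i in 1:20) {
      m <- random_rna_string(21)
      s <- random_rna_string(80)
      w <- sort(runif(3))
      v <- vapply(w, function(ww)
        seed_complementarity_score(m, s, wobble_weight = ww)$value, 0)
      expect_true(all(diff(v) >= -1e-12))
    }
  })
})

test_that("duplex DP reproduces closed-form helices and the no-duplex case", {
  tab <- energy_table("builtin-v1")
  # 6 A:U pairs: initiation + 5 AU/AU stacks
  expect_equal(duplex_free_energy_dp("UUUUUU", "AAAAAA"),
               tab$init + 5 * tab$stacks["UA", "UA"])
  expect_equal(duplex_free_energy_dp("AAAAAA", "AAAAAA"), 0)
  expect_error(duplex_free_energy_dp("ACGU", "ACGU", table = "no-such-table"),
               "unknown energy table")
})

test_that("duplex DP equals the exhaustive enumeration on short pairs", {
  withr::with_seed(31, {
    for (i in 1:80) {
      a <- random_rna_string(sample(2:8, 1))
      b <- random_rna_string(sample(2:8, 1))
      expect_equal(duplex_free_energy_dp(a, b),
                   duplex_free_energy_exhaustive(a, b), tolerance = 1e-12)
    }
  })
})

test_that("duplex energy is never positive and improves under complementary extension", {
  withr::with_seed(41, {
    for (i in 1:40) {
      a <- random_rna_string(sample(4:12, 1))
      b <- random_rna_string(sample(4:12, 1))
      e <- duplex_free_energy_dp(a, b)
      expect_lte(e, 0)
      # append a complementary G:C helix to both sides
      e2 <- duplex_free_energy_dp(paste0(a, "GGGG"), paste0("CCCC", b))
      expect_lte(e2, e + 1e-12)
    }
  })
})

test_that("transcript scanning finds planted sites and breaks ties leftward", {
  mirna <- list(id = "m1", sequence = "UGACAGAAGAGAGUGAGCACA")
  site <- rna_reverse_complement(mirna$sequence)
  withr::with_seed(51, {
    left <- random_rna_string(40)
    right <- random_rna_string(60)
  })
  tx <- list(gene_symbol = "G1", sequence = paste0(left, site, right))
  spec <- predictor_spec("dup", "duplex", window = 21L, step = 1L)
  out <- scan_transcript(mirna, tx, spec)
  expect_equal(out$site$start, 40)
  expect_equal(out$value, duplex_free_energy_dp(mirna$sequence, site))

  # two identical best sites: the leftmost is reported
  tx2 <- list(gene_symbol = "G2",
              sequence = paste0(left, site, left, site, right))
  out2 <- scan_transcript(mirna, tx2, spec)
  expect_equal(out2$site$start, 40)

  # step-1 scan equals the every-offset oracle on a short transcript
  withr::with_seed(52, { short <- random_rna_string(60) })
  m2 <- list(id = "m2", sequence = random_rna_string(18))
  got <- scan_transcript(m2, list(gene_symbol = "G3", sequence = short),
                         predictor_spec("dup", "duplex", window = 18L, step = 1L))
  offs <- vapply(0:(60 - 18), function(s)
    duplex_free_energy_dp(m2$sequence, substr(short, s + 1, s + 18)), 0)
  expect_equal(got$value, min(offs))
  expect_equal(got$site$start, which.min(offs) - 1L)
})

test_that("a transcript shorter than the window is scanned as one window", {
  mirna <- list(id = "m1", sequence = strrep("U", 18))
  tx <- list(gene_symbol = "G1", sequence = strrep("A", 27))
  spec <- predictor_spec("dup", "duplex", window = 28L, step = 7L)
  expect_warning(out <- scan_transcript(mirna, tx, spec), "whole-transcript")
  expect_equal(out$site$start, 0)
  expect_equal(out$site$end, 27)
})

test_that("the predictor ensemble records one output per spec", {
  withr::with_seed(61, {
    mirna <- list(id = "m1", sequence = random_rna_string(21))
    tx <- list(gene_symbol = "G1", species = "synthetic",
               sequence = random_rna_string(120))
  })
  nine <- lapply(1:9, function(i)
    predictor_spec(paste0("p", i),
                   c("seed", "duplex", "seed_anchored_duplex")[(i %% 3) + 1]))
  cand <- run_predictor_ensemble(mirna, tx, nine)
  expect_length(cand$outputs, 9)
  expect_true(cand$complete)
  expect_equal(cand$n_specs, 9)

  one <- run_predictor_ensemble(mirna, tx, list(predictor_spec("d", "duplex")))
  fv <- build_feature_vector(one)
  expect_equal(fv$PS, 0)
  expect_equal(fv$n_prob, 0)

  expect_error(run_predictor_ensemble(mirna, tx, list()), "non-empty")
  expect_error(
    run_predictor_ensemble(mirna, tx, list(predictor_spec("d", "duplex"),
                                           predictor_spec("d", "seed"))),
    "unique")
})

test_that("a failing plugin yields an incomplete candidate with no usable output", {
  withr::with_seed(62, {
    mirna <- list(id = "m1", sequence = random_rna_string(21))
    tx <- list(gene_symbol = "G1", sequence = random_rna_string(80))
  })
  bad <- predictor_spec("broken", "plugin", command = "false")
  expect_warning(cand <- run_predictor_ensemble(mirna, tx, list(bad)),
                 "failed")
  expect_false(cand$complete)
  expect_true(is.na(cand$outputs[[1]]$value))
  expect_error(build_feature_vector(cand), "no usable")
})

test_that("a working plugin contributes its emitted row", {
  skip_on_os("windows")
  cmd <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "printf 'ext\\tprobability\\t0.75\\n'"), cmd)
  Sys.chmod(cmd, "0755")
  withr::with_seed(63, {
    mirna <- list(id = "m1", sequence = random_rna_string(21))
    tx <- list(gene_symbol = "G1", sequence = random_rna_string(80))
  })
  cand <- run_predictor_ensemble(mirna, tx,
                                 list(predictor_spec("ext", "plugin",
                                                     command = cmd)))
  expect_true(cand$complete)
  expect_equal(cand$outputs[[1]]$value, 0.75)
  expect_equal(build_feature_vector(cand)$PS, 0.75)
})
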