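test_that("ddCt fold changes match hand calculations", {
  tab <- make_ct_table(list(
    control = list(s1 = c(HK = 20, tgt = 24)),
    treated = list(s2 = c(HK = 20, tgt = 25))))
  rec <- delta_delta_ct(tab, "control", "treated")
  expect_equal(rec$ddct, 1)
  expect_equal(rec$fold_change, 0.5)

  # identical groups: FC exactly 1 for every id
  tab2 <- make_ct_table(list(
    g1 = list(s1 = c(HK = 20, a = 25, b = 30)),
    g2 = list(s2 = c(HK = 20, a = 25, b = 30))))
  rec2 <- delta_delta_ct(tab2, "g1", "g2")
  expect_equal(rec2$fold_change, c(1, 1))

  # one cycle lower in the contrast group doubles expression
  tab3 <- make_ct_table(list(
    g1 = list(s1 = c(HK = 20, a = 25)),
    g2 = list(s2 = c(HK = 20, a = 24))))
  expect_equal(delta_delta_ct(tab3, "g1", "g2")$fold_change, 2)
})

test_that("swapping reference and contrast reciprocates every fold change", {
  cfg <- synth_config(seed = 19, n_genes = 20, replicates = 4)
  g <- gen_ct_table(cfg)
  fwd <- delta_delta_ct(g$table, "ND", "HFD")
  rev <- delta_delta_ct(g$table, "HFD", "ND")
  expect_equal(fwd$fold_change[match(rev$id, fwd$id)] * rev$fold_change,
               rep(1, nrow(rev)))
})

test_that("ddCt handles missing ids and housekeeper-free samples", {
  tab <- make_ct_table(list(
    g1 = list(s1 = c(HK = 20, a = 25, b = 28)),
    g2 = list(s2 = c(HK = 20, a = 24))))
  expect_warning(rec <- delta_delta_ct(tab, "g1", "g2"), "skipped")
  expect_equal(rec$id, "a")

  no_hk <- make_ct_table(list(
    g1 = list(s1 = c(HK = 20, a = 25), s2 = c(a = 99)),
    g2 = list(s3 = c(HK = 20, a = 24))))
  expect_warning(rec2 <- delta_delta_ct(no_hk, "g1", "g2"), "housekeeping")
  expect_equal(rec2$fold_change, 2)  # the housekeeper-free sample is dropped

  multi_hk <- make_ct_table(list(
    g1 = list(s1 = c(HK = 19, HK2 = 21, a = 25)),
    g2 = list(s2 = c(HK = 19, HK2 = 21, a = 24))))
  multi_hk$is_housekeeping <- multi_hk$target_id %in% c("HK", "HK2")
  expect_equal(delta_delta_ct(multi_hk, "g1", "g2")$fold_change, 2)
})

test_that("fold-change classification uses strict thresholds", {
  expect_equal(classify_fold_change(1.6), "up")
  expect_equal(classify_fold_change(1.50), "unchanged")
  expect_equal(classify_fold_change(0.4), "down")
  expect_equal(classify_fold_change(0.5), "unchanged")
  expect_equal(classify_fold_change(c(2, 1, 0.1)), c("up", "unchanged", "down"))
  expect_error(classify_fold_change(0), "positive")
  expect_error(classify_fold_change(1, up_threshold = 0.4), "below")
})

test_that("panel summaries report the printed percentage style", {
  mk <- function(n_up, n_down, n = 84) {
    data.frame(id = sprintf("g%02d", 1:n), contrast = "HFD vs ND",
               ddct = 0, fold_change = 1,
               class = c(rep("up", n_up), rep("down", n_down),
                         rep("unchanged", n - n_up - n_down)),
               stringsAsFactors = FALSE)
  }
  s <- summarize_panel(mk(45, 7))
  expect_equal(s$pct_up, 53.6)
  expect_equal(s$pct_down, 8.3)
  expect_equal(s$n_up + s$n_down + s$n_unchanged, s$n_total)

  s2 <- summarize_panel(mk(8, 39))
  expect_equal(s2$pct_down, 46.4)

  s3 <- summarize_panel(mk(0, 0))
  expect_equal(s3$pct_up, 0)
  expect_equal(s3$pct_down, 0)

  shuffled <- withr::with_seed(4, mk(45, 7)[sample(84), ])
  expect_equal(summarize_panel(shuffled)$n_up, 45)

  mixed <- mk(1, 1); mixed$contrast[1] <- "other"
  expect_error(summarize_panel(mixed), "contrasts")
})

test_that("miRNA relative levels reproduce the 2^-ddCt arithmetic", {
  # miRNA Ct equal to 5S in every group -> level 1 everywhere
  tab <- make_ct_table(list(
    ND = list(s1 = c(HK = 20, m1 = 20)),
    HFD = list(s2 = c(HK = 21, m1 = 21))))
  tab$target_id[tab$target_id == "HK"] <- "5S"
  lev <- mirna_relative_levels(tab, "5S", "ND")
  expect_equal(unname(lev$levels["m1", ]), c(1, 1))

  # a 3-cycle decrease vs reference with equal 5S -> level 8
  tab2 <- make_ct_table(list(
    ND = list(s1 = c(HK = 20, m1 = 25)),
    pool = list(s2 = c(HK = 20, m1 = 22))))
  tab2$target_id[tab2$target_id == "HK"] <- "5S"
  lev2 <- mirna_relative_levels(tab2, "5S", "ND")
  expect_equal(lev2$levels["m1", "pool"], 8)

  # multi-group, multi-miRNA fixture against a spreadsheet-style recomputation
  withr::with_seed(23, {
    groups <- c("ND", "HFD", "pool")
    cts <- lapply(groups, function(g) {
      lapply(1:3, function(r) {
        v <- c(20 + rnorm(1, 0, 0.2), runif(4, 22, 30))
        names(v) <- c("5S", paste0("miR-", 1:4))
        v
      })
    })
    names(cts) <- groups
    for (g in groups) names(cts[[g]]) <- paste0(g, "_", 1:3)
  })
  tab3 <- make_ct_table(cts)
  tab3$is_housekeeping <- tab3$target_id == "5S"
  lev3 <- mirna_relative_levels(tab3, "5S", "ND")
  for (g in c("HFD", "pool")) {
    for (m in paste0("miR-", 1:4)) {
      dct <- function(gr) {
        gt <- tab3[tab3$group == gr, ]
        mean(gt$ct[gt$target_id == m]) - mean(gt$ct[gt$target_id == "5S"])
      }
      expect_equal(lev3$levels[m, g], 2^-(dct(g) - dct("ND")),
                   tolerance = 1e-9)
    }
  }
})

test_that("sample size search matches the exact noncentral-t power oracle", {
  expect_identical(sample_size_for_power(4.0, 0.05, 0.8), 3L)
  expect_identical(sample_size_for_power(1.0, 0.05, 0.8), 17L)
  expect_identical(sample_size_for_power(100, 0.05, 0.8), 2L)
  # independent oracle: base R's continuous power solver, rounded up
  for (d in c(0.5, 1, 2, 4)) {
    oracle <- ceiling(stats::power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                          power = 0.8)$n - 1e-9)
    expect_equal(sample_size_for_power(d), as.integer(oracle))
  }
  expect_error(sample_size_for_power(0), "positive")
  expect_error(sample_size_for_power(-1), "positive")
})

test_that("sample size is monotone in effect size and target power", {
  d <- c(0.5, 1, 2, 4, 8)
  n_by_d <- vapply(d, sample_size_for_power, 1L)
  expect_true(all(diff(n_by_d) <= 0))
  pw <- c(0.5, 0.7, 0.8, 0.9, 0.99)
  n_by_p <- vapply(pw, function(p) sample_size_for_power(1, power = p), 1L)
  expect_true(all(diff(n_by_p) >= 0))
})

test_that("Ct tables round-trip through CSV", {
  cfg <- synth_config(seed = 29, n_genes = 5, replicates = 2)
  g <- gen_ct_table(cfg)
  path <- tempfile(fileext = ".csv")
  write.csv(g$table, path, row.names = FALSE, quote = FALSE)
  back <- read_ct_csv(path)
  expect_equal(back$ct, g$table$ct, tolerance = 1e-12)
  expect_identical(back$is_housekeeping, g$table$is_housekeeping)
})
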