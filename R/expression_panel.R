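# qPCR expression-panel quantification: 2^-ddCt fold changes against a
# housekeeping control and a reference group, the >1.50 / <0.5 significance
# classification, panel summaries, miRNA relative levels, and the exact
# noncentral-t sample-size computation.

#' Read a Ct table from CSV
#'
#' Expected columns: `sample_id,group,target_id,ct,is_housekeeping`.
#'
#' @param path CSV file path
#' @return data.frame with those columns; `is_housekeeping` coerced to
#'   logical
#' @export
read_ct_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "target_id", "ct", "is_housekeeping")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  df$is_housekeeping <- as.logical(df$is_housekeeping)
  if (any(!is.finite(df$ct))) stop("Ct values must be finite")
  df
}

# Per-group summaries used by the ddCt arithmetic: group mean Ct per target
# and the group housekeeping mean (arithmetic mean of per-sample housekeeper
# means, which equals a geometric mean on the expression scale). Samples
# without a housekeeping row are excluded with a warning.
group_ct_means <- function(table, group) {
  gt <- table[table$group == group, , drop = FALSE]
  if (nrow(gt) == 0) stop("group not present in Ct table: ", group)
  hk_by_sample <- tapply(gt$ct[gt$is_housekeeping],
                         gt$sample_id[gt$is_housekeeping], mean)
  samples <- unique(gt$sample_id)
  no_hk <- setdiff(samples, names(hk_by_sample))
  if (length(no_hk)) {
    warning(sprintf("excluding sample(s) without housekeeping rows in group %s: %s",
                    group, paste(no_hk, collapse = ", ")))
    gt <- gt[!gt$sample_id %in% no_hk, , drop = FALSE]
  }
  targets <- gt[!gt$is_housekeeping, , drop = FALSE]
  list(target_mean = tapply(targets$ct, targets$target_id, mean),
       hk_mean = mean(hk_by_sample[names(hk_by_sample) %in% gt$sample_id]))
}

#' Relative expression by the 2^-ddCt method
#'
#' For every non-housekeeping target id present in both groups:
#' dCt = mean Ct(id) - mean Ct(housekeeping) within each group,
#' ddCt = dCt(contrast) - dCt(reference), fold change = 2^-ddCt, classified
#' against the >1.50 / <0.5 thresholds. Ids present in only one group are
#' skipped with a warning.
#'
#' @param table Ct data.frame (see [read_ct_csv()])
#' @param reference_group,contrast_group group labels
#' @param up_threshold,down_threshold fold-change significance thresholds
#' @return data.frame of fold-change records: `id`, `contrast`, `ddct`,
#'   `fold_change`, `class`
#' @export
delta_delta_ct <- function(table, reference_group, contrast_group,
                           up_threshold = 1.50, down_threshold = 0.5) {
  ref <- group_ct_means(table, reference_group)
  con <- group_ct_means(table, contrast_group)
  ids <- intersect(names(con$target_mean), names(ref$target_mean))
  skipped <- union(setdiff(names(con$target_mean), ids),
                   setdiff(names(ref$target_mean), ids))
  if (length(skipped)) {
    warning("target id(s) missing in one group, skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(ids) == 0) stop("no target ids shared between the two groups")
  dct_ref <- ref$target_mean[ids] - ref$hk_mean
  dct_con <- con$target_mean[ids] - con$hk_mean
  ddct <- unname(dct_con - dct_ref)
  fc <- 2^(-ddct)
  data.frame(id = ids,
             contrast = paste(contrast_group, "vs", reference_group),
             ddct = ddct, fold_change = fc,
             class = classify_fold_change(fc, up_threshold, down_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a fold change against the significance thresholds
#'
#' Strict inequalities: `up` when FC > 1.50, `down` when FC < 0.5, otherwise
#' `unchanged`; values on a threshold are unchanged.
#'
#' @param fc positive fold-change vector
#' @param up_threshold,down_threshold thresholds (down < up required)
#' @return character vector with values `"up"`, `"down"`, `"unchanged"`
#' @export
classify_fold_change <- function(fc, up_threshold = 1.50,
                                 down_threshold = 0.5) {
  if (down_threshold >= up_threshold) stop("down threshold must be below up threshold")
  if (any(!is.finite(fc)) || any(fc <= 0)) stop("fold changes must be positive")
  ifelse(fc > up_threshold, "up", ifelse(fc < down_threshold, "down", "unchanged"))
}

#' Summarize a panel of fold-change records
#'
#' Counts up/down/unchanged genes for a single contrast and reports
#' percentages to one decimal place (half-up rounding).
#'
#' @param records data.frame of fold-change records from [delta_delta_ct()]
#' @return list of class `panel_summary`: `contrast`, `n_total`, `n_up`,
#'   `n_down`, `n_unchanged`, `pct_up`, `pct_down`
#' @export
summarize_panel <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no fold-change records")
  if (length(unique(records$contrast)) > 1) {
    stop("records mix multiple contrasts: ",
         paste(unique(records$contrast), collapse = ", "))
  }
  n <- nrow(records)
  n_up <- sum(records$class == "up")
  n_down <- sum(records$class == "down")
  structure(list(contrast = records$contrast[1], n_total = n, n_up = n_up,
                 n_down = n_down, n_unchanged = n - n_up - n_down,
                 pct_up = round_half_up(100 * n_up / n, 1),
                 pct_down = round_half_up(100 * n_down / n, 1)),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Panel summary [%s]: %d genes; %d up (%.1f%%), %d down (%.1f%%), %d unchanged\n",
              x$contrast, x$n_total, x$n_up, x$pct_up, x$n_down, x$pct_down,
              x$n_unchanged))
  invisible(x)
}

#' miRNA relative levels against a housekeeping RNA
#'
#' Applies the 2^-ddCt arithmetic to miRNA Ct rows normalized to a
#' housekeeping RNA (default 5S), contrasting every non-reference group with
#' the reference, and returns a miRNA x group matrix of relative levels
#' (reference column = 1).
#'
#' @param table Ct data.frame whose `target_id` holds miRNA ids and the
#'   housekeeper
#' @param housekeeper housekeeping RNA id (default `"5S"`)
#' @param reference_group reference group label
#' @return list: `levels` (miRNA x group matrix), `records` (stacked
#'   fold-change records for all contrasts)
#' @export
mirna_relative_levels <- function(table, housekeeper = "5S",
                                  reference_group) {
  if (!any(table$target_id == housekeeper)) {
    stop("housekeeper not present in table: ", housekeeper)
  }
  table$is_housekeeping <- table$target_id == housekeeper
  groups <- setdiff(unique(table$group), reference_group)
  recs <- do.call(rbind, lapply(groups, function(g) {
    delta_delta_ct(table, reference_group, g)
  }))
  mirnas <- sort(unique(recs$id))
  levels <- matrix(1, nrow = length(mirnas), ncol = length(groups) + 1,
                   dimnames = list(mirnas, c(reference_group, groups)))
  for (g in groups) {
    r <- recs[recs$contrast == paste(g, "vs", reference_group), ]
    levels[r$id, g] <- r$fold_change
  }
  list(levels = levels, records = recs)
}

# Exact power of the two-sided two-sample t-test (equal n and SD) at
# standardized effect size d: noncentral t with df = 2n-2 and
# noncentrality d * sqrt(n/2).
two_sample_t_power <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Sample size for a two-sample comparison
#'
#' Smallest integer n >= 2 per group such that the exact two-sided two-sample
#' t-test (noncentral t, df = 2n-2, noncentrality d*sqrt(n/2)) reaches the
#' target power.
#'
#' @param d standardized effect size (> 0)
#' @param alpha two-sided significance level
#' @param power target power
#' @param n_max search bound
#' @return integer n per group
#' @export
sample_size_for_power <- function(d, alpha = 0.05, power = 0.8,
                                  n_max = 10000L) {
  if (!is.finite(d) || d <= 0) stop("effect size d must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("target power must lie in (0, 1)")
  for (n in 2:n_max) {
    if (two_sample_t_power(n, d, alpha) >= power) return(as.integer(n))
  }
  stop("target power not reached within n_max = ", n_max)
}
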