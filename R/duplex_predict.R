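# Per-algorithm interaction predictors. Three built-in surrogates (seed
# complementarity, full duplex free-energy DP, seed-anchored duplex DP) plus
# an external-process plugin contract supply the energies E_i and
# probabilities SCORE_i that the ensemble scores aggregate.

.energy_table_cache <- new.env(parent = emptyenv())

#' Load a duplex nearest-neighbour energy table
#'
#' The built-in table `"builtin-v1"` ships with the package as a versioned
#' TSV: stacking energies for all Watson-Crick and G:U pair steps, an affine
#' bulge/internal-loop penalty (`loop_open` + `loop_ext` per unpaired base)
#' and a duplex initiation penalty of +4.1 kcal/mol.
#'
#' @param id table identifier (`"builtin-v1"`) or a path to a TSV in the same
#'   format
#' @return list with `stacks` (6x6 matrix over pair types AU, UA, CG, GC, GU,
#'   UG), `init`, `loop_open`, `loop_ext`, `id`, `hash`
#' @export
energy_table <- function(id = "builtin-v1") {
  key <- as.character(id)
  if (!is.null(.energy_table_cache[[key]])) return(.energy_table_cache[[key]])
  path <- if (identical(key, "builtin-v1")) {
    system.file("extdata", "duplex_energy_builtin_v1.tsv", package = "mircross")
  } else if (file.exists(key)) key else ""
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown energy table id: ", key)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pair_names <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stacks <- matrix(NA_real_, 6, 6, dimnames = list(pair_names, pair_names))
  params <- list()
  for (p in parts) {
    if (p[[1]] == "param") params[[p[[2]]]] <- as.numeric(p[[3]])
    else if (p[[1]] == "stack") stacks[p[[2]], p[[3]]] <- as.numeric(p[[4]])
  }
  if (anyNA(stacks)) stop("energy table is missing stack entries: ", path)
  tab <- list(stacks = stacks, init = params$init, loop_open = params$loop_open,
              loop_ext = params$loop_ext, id = key,
              hash = fingerprint(list(stacks, params)))
  .energy_table_cache[[key]] <- tab
  tab
}

#' Seed complementarity score
#'
#' Slides the miRNA along the site (antiparallel, site read 3'->5' against
#' the miRNA 5'->3') and scores only the seed positions: each Watson-Crick
#' match counts 1, each G:U wobble counts `wobble_weight`; the sum is divided
#' by the seed length and maximized over all offsets, giving a probability-
#' like score in [0, 1].
#'
#' @param mirna_seq miRNA sequence, 5'->3' RNA
#' @param site_seq candidate site sequence (sense strand), at least as long
#'   as the miRNA
#' @param seed_span 1-based inclusive positions of the seed on the miRNA
#'   (default 2-8)
#' @param wobble_weight weight of a G:U pair relative to a Watson-Crick pair
#' @return list of class `predictor_output` with `predictor_id`, `kind`
#'   (`"probability"`), `value`, and `site` (start/end, 0-based half-open on
#'   the site sequence)
#' @export
seed_complementarity_score <- function(mirna_seq, site_seq,
                                       seed_span = c(2L, 8L),
                                       wobble_weight = 0.5) {
  m <- rna_to_int(mirna_seq)
  s <- rna_to_int(site_seq)
  if (length(s) < length(m)) stop("site shorter than miRNA")
  if (seed_span[1] < 1 || seed_span[2] > length(m) || seed_span[1] > seed_span[2]) {
    stop("seed span must lie within the miRNA")
  }
  res <- .seed_scan_cpp(m, s, as.integer(seed_span[1]), as.integer(seed_span[2]),
                        wobble_weight)
  predictor_output("seed", "probability", res$score,
                   site = list(start = res$start, end = res$end))
}

#' Minimum free energy of an intermolecular miRNA:site duplex
#'
#' Dynamic program over all antiparallel duplex alignments of the miRNA
#' (5'->3') against the window (read 3'->5'), allowing bulges and internal
#' loops with an affine penalty and no intramolecular structure. Stacking
#' energies, loop penalties and the duplex-initiation penalty come from the
#' energy table. Returns 0 when no alignment achieves negative energy ("no
#' stable duplex").
#'
#' @param mirna_seq miRNA sequence, 5'->3' RNA
#' @param window_seq window sequence (sense strand), 5'->3' RNA
#' @param table energy table id or object from [energy_table()]
#' @return duplex free energy in kcal/mol (<= 0)
#' @export
duplex_free_energy_dp <- function(mirna_seq, window_seq, table = "builtin-v1") {
  if (!is.list(table)) table <- energy_table(table)
  .duplex_dp_energy_cpp(rna_to_int(mirna_seq), rna_to_int(window_seq),
                        table$stacks, table$init, table$loop_open,
                        table$loop_ext)
}

#' Brute-force duplex free energy (reference implementation)
#'
#' Exhaustively enumerates every monotone set of base pairs between the two
#' sequences (antiparallel) and scores it with the same energy table:
#' initiation + stacking for adjacent pairs + affine loop penalties across
#' unpaired stretches. Exponential in sequence length; intended as an
#' independent check of [duplex_free_energy_dp()] on sequences of length
#' <= 8.
#'
#' @inheritParams duplex_free_energy_dp
#' @return duplex free energy in kcal/mol (<= 0)
#' @export
duplex_free_energy_exhaustive <- function(mirna_seq, window_seq,
                                          table = "builtin-v1") {
  if (!is.list(table)) table <- energy_table(table)
  pair_names <- c("AU", "UA", "CG", "GC", "GU", "UG")
  a <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(window_seq, "", fixed = TRUE)[[1]])  # antiparallel
  pt <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% pair_names) p else NA_character_
  }
  n <- length(a); m <- length(b)
  best <- 0
  # recursive enumeration: extend a partial duplex whose last pair is (i, j)
  extend <- function(i, j, e) {
    if (e < best) best <<- e
    if (i >= n || j >= m) return(invisible())
    for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
      p2 <- pt(a[i2], b[j2])
      if (is.na(p2)) next
      gap <- (i2 - i - 1) + (j2 - j - 1)
      step <- if (gap == 0) table$stacks[pt(a[i], b[j]), p2]
              else table$loop_open + table$loop_ext * gap
      extend(i2, j2, e + step)
    }
  }
  for (i in 1:n) for (j in 1:m) {
    if (!is.na(pt(a[i], b[j]))) extend(i, j, table$init)
  }
  min(0, best)
}

#' Construct a predictor output record
#'
#' @param predictor_id predictor label
#' @param kind `"energy"` (kcal/mol, <= 0; 0 encodes no stable duplex) or
#'   `"probability"` (in [0, 1])
#' @param value numeric output
#' @param site optional list with `start`/`end` (0-based half-open on the
#'   transcript) and optionally `gene_symbol`, `duplex_energy`
#' @return list of class `predictor_output`
#' @export
predictor_output <- function(predictor_id, kind = c("energy", "probability"),
                             value, site = NULL) {
  kind <- match.arg(kind)
  if (!is.na(value)) {
    if (kind == "probability" && (value < 0 || value > 1)) {
      stop("probability output outside [0, 1]: ", value)
    }
    if (kind == "energy" && value > 0) {
      stop("energy output must be <= 0 (0 = no stable duplex): ", value)
    }
  }
  structure(list(predictor_id = predictor_id, kind = kind, value = value,
                 site = site), class = "predictor_output")
}

#' Specify a predictor
#'
#' A spec fully determines the predictor's output for a given miRNA/transcript
#' pair. Built-in types: `"seed"` (seed complementarity over the whole
#' transcript), `"duplex"` (windowed duplex DP scan), `"seed_anchored_duplex"`
#' (duplex DP on a window anchored at the best seed site), and `"plugin"`
#' (external command emitting one `predictor_id<TAB>kind<TAB>value` row).
#'
#' @param predictor_id unique predictor label
#' @param type one of `"seed"`, `"duplex"`, `"seed_anchored_duplex"`,
#'   `"plugin"`
#' @param ... parameters: `seed_span`, `wobble_weight`, `energy_table_id`,
#'   `window`, `step`, `flank`, `command` (plugin)
#' @return list of class `predictor_spec`
#' @export
predictor_spec <- function(predictor_id,
                           type = c("seed", "duplex", "seed_anchored_duplex",
                                    "plugin"), ...) {
  type <- match.arg(type)
  params <- list(...)
  defaults <- list(seed_span = c(2L, 8L), wobble_weight = 0.5,
                   energy_table_id = "builtin-v1", window = 28L, step = 7L,
                   flank = 4L)
  for (nm in names(defaults)) {
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  }
  kind <- if (type == "seed") "probability" else "energy"
  if (type == "plugin" && is.null(params$command)) {
    stop("plugin predictor needs a 'command' parameter")
  }
  if (type == "plugin" && !is.null(params$kind)) kind <- params$kind
  structure(list(predictor_id = predictor_id, type = type, kind = kind,
                 params = params), class = "predictor_spec")
}

#' Default built-in predictor ensemble
#'
#' Three surrogate predictors standing in for an external multi-algorithm
#' stack: seed complementarity, a windowed duplex free-energy scan, and a
#' duplex evaluation anchored at the best seed site.
#'
#' @param window scan window length (>= miRNA length)
#' @param step scan step
#' @return list of `predictor_spec`
#' @export
default_predictor_specs <- function(window = 28L, step = 7L) {
  list(predictor_spec("seed", "seed"),
       predictor_spec("duplex_mfe", "duplex", window = window, step = step),
       predictor_spec("seed_duplex", "seed_anchored_duplex",
                      window = window, step = step))
}

#' Scan a transcript with one predictor
#'
#' Evaluates the predictor on every window (for windowed predictors) or over
#' all offsets (seed) and returns the best binding site: minimum energy or
#' maximum probability, ties broken by smallest start coordinate. A
#' transcript shorter than the window is evaluated as a single
#' whole-transcript window with a warning.
#'
#' @param mirna one-row data.frame (or list) with `id` and `sequence`
#' @param transcript one-row data.frame (or list) with `gene_symbol` and
#'   `sequence`
#' @param spec a [predictor_spec()]
#' @param window,step optional overrides of the spec's scan parameters
#' @return `predictor_output` whose `site` carries `gene_symbol`, `start`,
#'   `end` and, for energy predictors, `duplex_energy`
#' @export
scan_transcript <- function(mirna, transcript, spec,
                            window = NULL, step = NULL) {
  m <- rna_to_int(mirna$sequence)
  s <- rna_to_int(transcript$sequence)
  w <- as.integer(if (is.null(window)) spec$params$window else window)
  st <- as.integer(if (is.null(step)) spec$params$step else step)
  if (st < 1) stop("step must be >= 1")
  if (w < length(m)) stop("window must be at least the miRNA length")
  if (length(s) < w) {
    warning(sprintf("transcript %s (%d nt) shorter than window (%d nt); using one whole-transcript window",
                    transcript$gene_symbol, length(s), w))
  }
  if (spec$type == "seed") {
    out <- seed_complementarity_score(mirna$sequence, transcript$sequence,
                                      spec$params$seed_span,
                                      spec$params$wobble_weight)
    out$predictor_id <- spec$predictor_id
    out$site$gene_symbol <- transcript$gene_symbol
    return(out)
  }
  tab <- energy_table(spec$params$energy_table_id)
  if (spec$type == "duplex") {
    res <- .duplex_scan_cpp(m, s, w, st, tab$stacks, tab$init, tab$loop_open,
                            tab$loop_ext)
    return(predictor_output(spec$predictor_id, "energy", res$energy,
                            site = list(gene_symbol = transcript$gene_symbol,
                                        start = res$start, end = res$end,
                                        duplex_energy = res$energy)))
  }
  if (spec$type == "seed_anchored_duplex") {
    anchor <- .seed_scan_cpp(m, s, as.integer(spec$params$seed_span[1]),
                             as.integer(spec$params$seed_span[2]),
                             spec$params$wobble_weight)
    fl <- as.integer(spec$params$flank)
    from <- max(0L, anchor$start - fl)
    to <- min(length(s), anchor$end + fl)
    e <- .duplex_dp_energy_cpp(m, s[(from + 1):to], tab$stacks, tab$init,
                               tab$loop_open, tab$loop_ext)
    return(predictor_output(spec$predictor_id, "energy", e,
                            site = list(gene_symbol = transcript$gene_symbol,
                                        start = from, end = to,
                                        duplex_energy = e)))
  }
  stop("scan_transcript does not handle predictor type: ", spec$type)
}

# Run an external plugin predictor: the command receives the miRNA and
# transcript sequences as two arguments and must print one TSV row
# `predictor_id<TAB>kind<TAB>value`. Any failure yields an NA output.
run_plugin_predictor <- function(mirna, transcript, spec) {
  row <- tryCatch({
    out <- suppressWarnings(
      system2(spec$params$command, args = c(mirna$sequence, transcript$sequence),
              stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) stop("plugin exit status ", status)
    fields <- strsplit(out[1], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop("plugin emitted a malformed row")
    predictor_output(spec$predictor_id, fields[2], as.numeric(fields[3]),
                     site = list(gene_symbol = transcript$gene_symbol))
  }, error = function(e) {
    warning(sprintf("plugin predictor '%s' failed: %s", spec$predictor_id,
                    conditionMessage(e)))
    predictor_output(spec$predictor_id, spec$kind, NA_real_,
                     site = list(gene_symbol = transcript$gene_symbol))
  })
  row
}

#' Run a predictor ensemble on one miRNA/transcript pair
#'
#' Evaluates every predictor at its best site and collects the outputs into
#' an interaction candidate. A failing plugin is recorded as a missing output
#' and flags the candidate incomplete.
#'
#' @param mirna one-row data.frame (or list) with `id` and `sequence`
#' @param transcript one-row data.frame (or list) with `gene_symbol`,
#'   `sequence` and optionally `species`
#' @param specs non-empty list of [predictor_spec()] with unique ids
#' @return list of class `interaction_candidate`: `mirna_id`, `gene_symbol`,
#'   `species`, `outputs` (list of `predictor_output`), `n_specs`, `complete`
#' @export
run_predictor_ensemble <- function(mirna, transcript,
                                   specs = default_predictor_specs()) {
  if (length(specs) == 0) stop("predictor spec list must be non-empty")
  ids <- vapply(specs, `[[`, "", "predictor_id")
  if (anyDuplicated(ids)) stop("predictor ids must be unique")
  outputs <- lapply(specs, function(sp) {
    if (sp$type == "plugin") run_plugin_predictor(mirna, transcript, sp)
    else scan_transcript(mirna, transcript, sp)
  })
  usable <- vapply(outputs, function(o) is.finite(o$value), TRUE)
  structure(list(mirna_id = mirna$id, gene_symbol = transcript$gene_symbol,
                 species = if (!is.null(transcript$species)) transcript$species
                           else NA_character_,
                 outputs = outputs, n_specs = length(specs),
                 complete = all(usable)),
            class = "interaction_candidate")
}
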