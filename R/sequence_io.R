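#' Normalize a raw nucleotide string to RNA
#'
#' Uppercases, converts DNA thymine to uracil, and rejects any character
#' outside the RNA alphabet. DNA input is therefore accepted silently;
#' ambiguity codes are not.
#'
#' @param raw character vector of nucleotide strings
#' @return character vector of uppercase RNA strings (A/C/G/U)
#' @export
#' @examples
#' normalize_rna("acgt")  # "ACGU"
normalize_rna <- function(raw) {
  if (length(raw) == 0 || any(!nzchar(raw))) {
    stop("empty sequence cannot be normalized")
  }
  out <- chartr("T", "U", toupper(raw))
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("disallowed character '%s' at position %d in sequence '%s'",
                 substr(out[i], bad[i], bad[i]), bad[i], raw[i]))
  }
  out
}

#' Read mature miRNA sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the record id; an
#' optional `species=` key in the description is carried through. Sequences
#' are normalized to uppercase RNA (T converted to U).
#'
#' @param path FASTA file path
#' @param species default species tag when the header carries none
#' @param min_length minimum length required for scanning operations
#' @return data.frame with columns `id`, `sequence`, `length`, `species`,
#'   in file order
#' @export
read_mirna_fasta <- function(path, species = NA_character_, min_length = 16L) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("no records in FASTA file: ", path)
  headers <- names(recs)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  sp <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("species=\\S+", h))
    if (length(m)) sub("^species=", "", m) else NA_character_
  }, "", USE.NAMES = FALSE)
  seqs <- vapply(seq_along(recs), function(i) {
    tryCatch(normalize_rna(as.character(recs[[i]])),
             error = function(e) stop(sprintf("record '%s': %s", ids[i],
                                              conditionMessage(e)), call. = FALSE))
  }, "")
  lens <- nchar(seqs)
  if (any(lens < min_length)) {
    stop(sprintf("miRNA '%s' shorter than the %d nt minimum for scanning",
                 ids[which(lens < min_length)[1]], min_length))
  }
  data.frame(id = ids, sequence = seqs, length = lens,
             species = ifelse(is.na(sp), species, sp),
             stringsAsFactors = FALSE)
}

#' Read a gene-panel manifest
#'
#' Tab-separated file with header `gene_symbol<TAB>pathway`. Gene symbols are
#' uppercased; duplicates are an error. If `expected_size` is given the entry
#' count must match it.
#'
#' @param path manifest TSV path
#' @param panel_name free-text panel label
#' @param expected_size declared panel size (e.g. 84), or NULL to skip check
#' @return data.frame with columns `gene_symbol`, `pathway`; attribute
#'   `panel_name`
#' @export
read_panel_manifest <- function(path, panel_name = basename(path),
                                expected_size = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!all(c("gene_symbol", "pathway") %in% names(df))) {
    stop("manifest must have columns 'gene_symbol' and 'pathway'")
  }
  df$gene_symbol <- toupper(df$gene_symbol)
  dup <- df$gene_symbol[duplicated(df$gene_symbol)]
  if (length(dup)) stop("duplicate gene symbols in manifest: ",
                        paste(unique(dup), collapse = ", "))
  if (!is.null(expected_size) && nrow(df) != expected_size) {
    stop(sprintf("manifest has %d entries, declared panel size is %d",
                 nrow(df), expected_size))
  }
  attr(df, "panel_name") <- panel_name
  df
}

#' Read transcript regions from FASTA against a panel manifest
#'
#' Headers use the convention `>id gene=SYMBOL [species=...] [region=...]`.
#' Every manifest gene is either matched to one record or reported missing;
#' records whose gene is not in the manifest are reported as extra. A gene
#' appearing twice in the FASTA is an error.
#'
#' @param path FASTA file path
#' @param manifest data.frame from [read_panel_manifest()]
#' @param species default species tag
#' @param region_kind default region kind ("3UTR", "CDS" or "full")
#' @return list with `regions` (data.frame: gene_symbol, species, region_kind,
#'   sequence, length), `missing` (manifest genes without a record) and
#'   `extra` (record genes outside the manifest)
#' @export
read_transcript_fasta <- function(path, manifest, species = NA_character_,
                                  region_kind = "3UTR") {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("no records in FASTA file: ", path)
  headers <- names(recs)
  field <- function(h, key, default) {
    m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
    if (length(m)) sub(paste0("^", key, "="), "", m) else default
  }
  genes <- toupper(vapply(seq_along(headers), function(i) {
    g <- field(headers[i], "gene", NA_character_)
    if (is.na(g)) strsplit(headers[i], "\\s+")[[1]][1] else g
  }, ""))
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene in transcript FASTA: ",
                        paste(unique(dup), collapse = ", "))
  seqs <- vapply(seq_along(recs), function(i) {
    tryCatch(normalize_rna(as.character(recs[[i]])),
             error = function(e) stop(sprintf("record '%s': %s", genes[i],
                                              conditionMessage(e)), call. = FALSE))
  }, "")
  regions <- data.frame(
    gene_symbol = genes,
    species = vapply(headers, field, "", key = "species", default = species,
                     USE.NAMES = FALSE),
    region_kind = vapply(headers, field, "", key = "region", default = region_kind,
                         USE.NAMES = FALSE),
    sequence = seqs, length = nchar(seqs), stringsAsFactors = FALSE)
  in_manifest <- regions$gene_symbol %in% manifest$gene_symbol
  list(regions = regions[in_manifest, , drop = FALSE],
       missing = setdiff(manifest$gene_symbol, genes),
       extra = regions$gene_symbol[!in_manifest])
}

#' Write miRNA records to FASTA
#'
#' @param mirnas data.frame as returned by [read_mirna_fasta()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mirna_fasta <- function(mirnas, path) {
  x <- Biostrings::BStringSet(mirnas$sequence)
  names(x) <- ifelse(is.na(mirnas$species), mirnas$id,
                     paste0(mirnas$id, " species=", mirnas$species))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write transcript regions to FASTA
#'
#' Emits the `gene=` header convention understood by
#' [read_transcript_fasta()].
#'
#' @param regions data.frame with gene_symbol, species, region_kind, sequence
#' @param path output path
#' @return `path`, invisibly
#' @export
write_transcript_fasta <- function(regions, path) {
  x <- Biostrings::BStringSet(regions$sequence)
  names(x) <- sprintf("%s gene=%s species=%s region=%s", regions$gene_symbol,
                      regions$gene_symbol, regions$species, regions$region_kind)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
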