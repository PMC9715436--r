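#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), as conventional in
#' reported percentages; base `round()` rounds half to even.
#'
#' @param x numeric vector (non-negative in all package uses)
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# FNV-1a 32-bit hash of a serialized R object; used only to fingerprint
# configurations and training sets in output headers / model bundles.
# Arithmetic stays exact in doubles: the multiply is split so no intermediate
# exceeds 2^41.
fingerprint <- function(object) {
  bytes <- as.integer(serialize(object, connection = NULL, version = 2))
  if (length(bytes) > 20000) {
    bytes <- c(bytes[1:20000], length(bytes) %% 256)
  }
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), b)
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Ordered RNA alphabet used by the C++ kernels.
RNA_BASES <- c("A", "C", "G", "U")

# Map an RNA string to 0-based integer codes (A=0, C=1, G=2, U=3).
rna_to_int <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_BASES) - 1L
  if (anyNA(codes)) stop("sequence contains non-RNA characters: ", seq)
  codes
}

# Watson-Crick complement of an RNA string (no reversal).
rna_complement <- function(seq) {
  chartr("ACGU", "UGCA", seq)
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA string (A/C/G/U, uppercase)
#' @return the reverse complement, 5'->3'
#' @export
rna_reverse_complement <- function(seq) {
  paste(rev(strsplit(rna_complement(seq), "", fixed = TRUE)[[1]]), collapse = "")
}

#' Write a results table as TSV with a provenance header
#'
#' Writes `#`-prefixed comment lines recording the package version, a hash of
#' the supplied configuration object, and the seed, followed by a
#' tab-separated table with column names.
#'
#' @param df data.frame to write
#' @param path output file path
#' @param config optional configuration object hashed into the header
#' @param seed optional integer seed recorded in the header
#' @return `path`, invisibly
#' @export
write_result_tsv <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# mircross %s", as.character(packageVersion("mircross"))), con)
  if (!is.null(config)) writeLines(sprintf("# config_hash: %s", fingerprint(config)), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Derive a per-generator RNG sub-seed from a master seed and a fixed label so
# that adding a generator never perturbs the streams of the others.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
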