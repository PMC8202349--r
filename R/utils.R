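# Low-level sequence and quality helpers shared across modules.

# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8). Two symbols are
# compatible iff their masks intersect.
.iupac_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# 256-slot lookup by utf8 code; unknown symbols get mask 0 (match nothing).
.iupac_lut <- local({
  lut <- integer(256)
  lut[utf8ToInt(paste(names(.iupac_bits), collapse = "")) + 1L] <- .iupac_bits
  lut[utf8ToInt(paste(tolower(names(.iupac_bits)), collapse = "")) + 1L] <- .iupac_bits
  lut
})

seq_bits <- function(x) .iupac_lut[utf8ToInt(x) + 1L]

#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement honouring IUPAC degeneracy codes.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' dna_revcomp(c("ACGT", "GGNGA"))
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between phred+33 strings and integer scores
#'
#' @param qual Character scalar, a phred+33 encoded quality string.
#' @param scores Integer vector of phred scores.
#' @return `phred_scores()` returns an integer vector; `phred_string()`
#'   a character scalar.
#' @export
phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' @rdname phred_scores
#' @export
phred_string <- function(scores) intToUtf8(scores + 33L)

# Split one sequence into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_acgt <- function(x) !grepl("[^ACGT]", x)

# Longest common prefix of semicolon-delimited taxonomy paths (lowest common
# ancestor). Empty string if the paths disagree at the root.
taxonomy_lca <- function(paths) {
  paths <- unique(paths)
  if (length(paths) == 1L) return(paths)
  parts <- strsplit(paths, ";", fixed = TRUE)
  depth <- min(lengths(parts))
  keep <- 0L
  for (i in seq_len(depth)) {
    lev <- vapply(parts, `[[`, character(1), i)
    if (length(unique(lev)) > 1L) break
    keep <- i
  }
  if (keep == 0L) return("")
  paste(parts[[1]][seq_len(keep)], collapse = ";")
}
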