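#' Merge paired-end reads by overlap
#'
#' Reverse-complements the reverse read, scans all candidate overlap lengths
#' of at least `min_overlap`, and keeps the overlap with the lowest mismatch
#' fraction (ties resolved toward the longer overlap). A pair is merged only
#' if that fraction is at most `max_mismatch_density`; otherwise the pair is
#' reported as rejected, never silently dropped. Within the overlap the base
#' with the higher phred score wins and keeps its score (ties keep the
#' forward base).
#'
#' @param pairs Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (phred+33 quality strings; `seq2`/`qual2` as sequenced, i.e.
#'   reverse-strand).
#' @param min_overlap Minimum overlap length considered (default 10).
#' @param max_mismatch_density Maximum mismatch fraction tolerated in the
#'   chosen overlap (default 0.25).
#' @return Tibble with one row per input pair: `read_id`, `merged` (logical),
#'   `seq`, `qual` (NA when rejected), `overlap`, `mismatch_frac`, `reason`.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_density = 0.25) {
  stopifnot(min_overlap >= 1L, max_mismatch_density >= 0, max_mismatch_density <= 1)
  n <- nrow(pairs)
  out <- vector("list", n)
  rc2 <- dna_revcomp(pairs$seq2)
  for (i in seq_len(n)) {
    out[[i]] <- merge_one(
      pairs$seq1[i], pairs$qual1[i], rc2[i],
      phred_string(rev(phred_scores(pairs$qual2[i]))),
      min_overlap, max_mismatch_density
    )
  }
  dplyr::bind_cols(
    tibble(read_id = pairs$read_id),
    dplyr::bind_rows(out)
  )
}

# One pair; r2 already reverse-complemented, quals reversed.
merge_one <- function(s1, q1, s2, q2, min_overlap, max_density) {
  i1 <- utf8ToInt(s1); i2 <- utf8ToInt(s2)
  n1 <- length(i1); n2 <- length(i2)
  rejected <- tibble(
    merged = FALSE, seq = NA_character_, qual = NA_character_,
    overlap = NA_integer_, mismatch_frac = NA_real_, reason = "no_overlap"
  )
  lmax <- min(n1, n2)
  if (n1 == 0L || n2 == 0L || lmax < min_overlap) return(rejected)
  best_l <- NA_integer_; best_frac <- Inf
  for (l in seq(lmax, min_overlap)) {       # descending: ties keep longest
    mism <- sum(i1[(n1 - l + 1L):n1] != i2[seq_len(l)])
    frac <- mism / l
    if (frac < best_frac) {
      best_frac <- frac
      best_l <- l
      if (frac == 0) break                  # cannot be beaten
    }
  }
  if (best_frac > max_density) return(rejected)
  l <- best_l
  ov1 <- (n1 - l + 1L):n1
  ov2 <- seq_len(l)
  p1 <- phred_scores(q1); p2 <- phred_scores(q2)
  take2 <- p2[ov2] > p1[ov1]
  cons <- i1[ov1]; cons[take2] <- i2[ov2][take2]
  consq <- ifelse(take2, p2[ov2], p1[ov1])   # winning base keeps its own score
  tail2 <- if (n2 > l) p2[(l + 1L):n2] else integer(0)
  seq <- paste0(substr(s1, 1L, n1 - l), intToUtf8(cons), substr(s2, l + 1L, n2))
  qual <- phred_string(c(p1[seq_len(n1 - l)], consq, tail2))
  tibble(
    merged = TRUE, seq = seq, qual = qual,
    overlap = l, mismatch_frac = best_frac, reason = NA_character_
  )
}

#' Windowed phred quality filter
#'
#' A read is discarded iff any contiguous window of `window` bases has a mean
#' phred score strictly below `min_mean_phred`. Reads shorter than the window
#' are evaluated as a single full-length window.
#'
#' @param qual Character vector of phred+33 quality strings.
#' @param window Window length in nucleotides (default 50).
#' @param min_mean_phred Minimum tolerated window mean (default 20).
#' @return Logical vector: `TRUE` to keep.
#' @export
window_quality_keep <- function(qual, window = 50L, min_mean_phred = 20) {
  stopifnot(window >= 1L)
  vapply(qual, function(q) {
    p <- phred_scores(q)
    n <- length(p)
    if (n <= window) return(mean(p) >= min_mean_phred)
    s <- cumsum(p)
    means <- (s[window:n] - c(0, s[seq_len(n - window)])) / window
    !any(means < min_mean_phred)
  }, logical(1), USE.NAMES = FALSE)
}

#' @rdname window_quality_keep
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @return `filter_reads_quality()` returns the input tibble with logical
#'   `keep` and a `reason` column (`"low_quality_window"` for discards).
#' @export
filter_reads_quality <- function(reads, window = 50L, min_mean_phred = 20) {
  keep <- window_quality_keep(reads$qual, window, min_mean_phred)
  dplyr::mutate(reads,
    keep = keep,
    reason = dplyr::if_else(keep, NA_character_, "low_quality_window")
  )
}

#' Trim amplification primers off merged reads
#'
#' The forward primer is matched at the 5' end and the reverse-complemented
#' reverse primer at the 3' end, both anchored (amplicon reads begin at the
#' primers by construction) under IUPAC degeneracy with each primer's
#' `max_mismatches`. Both primer spans are removed; reads lacking either site
#' are rejected with a reason.
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual` (`qual` may be
#'   absent).
#' @param fwd,rev [primer_spec()] objects as supplied to the PCR (both given
#'   5' to 3' on their own strands).
#' @return Input tibble with `trimmed` (logical), trimmed `seq`/`qual`, and
#'   `reason` (`"no_forward_primer"` / `"no_reverse_primer"`).
#' @export
trim_primers <- function(reads, fwd, rev) {
  stopifnot(inherits(fwd, "primer_spec"), inherits(rev, "primer_spec"))
  fb <- seq_bits(fwd$iupac)
  rb <- seq_bits(dna_revcomp(rev$iupac))
  nf <- length(fb); nr <- length(rb)
  has_qual <- "qual" %in% names(reads)
  n <- nrow(reads)
  seq_out <- rep(NA_character_, n)
  qual_out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    bits <- seq_bits(s)
    ns <- length(bits)
    if (ns < nf + nr + 1L ||
        iupac_mismatches(fb, bits[seq_len(nf)]) > fwd$max_mismatches) {
      reason[i] <- "no_forward_primer"
      next
    }
    if (iupac_mismatches(rb, bits[(ns - nr + 1L):ns]) > rev$max_mismatches) {
      reason[i] <- "no_reverse_primer"
      next
    }
    ok[i] <- TRUE
    seq_out[i] <- substr(s, nf + 1L, ns - nr)
    if (has_qual) qual_out[i] <- substr(reads$qual[i], nf + 1L, ns - nr)
  }
  out <- dplyr::mutate(reads, trimmed = ok, seq = seq_out, reason = reason)
  if (has_qual) out$qual <- qual_out
  out
}

#' Read and write FASTQ as tibbles
#'
#' Thin wrappers around Biostrings' phred+33 FASTQ support, returning and
#' accepting tibbles with columns `read_id`, `seq`, `qual`.
#'
#' @param path File path.
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @return `read_fastq()` returns a tibble; `write_fastq()` its input,
#'   invisibly.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns here
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  )
  tibble(
    read_id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(reads)
}
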