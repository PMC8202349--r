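#' Describe an amplification primer
#'
#' A primer is an IUPAC-degenerate oligo matched against read ends (or
#' reference sequences) with at most `max_mismatches` mismatching positions.
#' Degeneracy is resolved by bitmask intersection, so `N` in either the
#' primer or the read matches anything.
#'
#' @param name Label used in logs.
#' @param iupac Primer sequence over the IUPAC alphabet, 5' to 3'.
#' @param max_mismatches Mismatches tolerated when matching (default 0).
#' @return A `primer_spec` object.
#' @export
#' @examples
#' primer_spec("A189F", "GGNGACTGGGACTTCTGG")
primer_spec <- function(name, iupac, max_mismatches = 0L) {
  iupac <- toupper(iupac)
  stopifnot(nzchar(iupac), max_mismatches >= 0, max_mismatches < nchar(iupac))
  if (any(seq_bits(iupac) == 0L)) {
    abort(paste0("primer '", name, "' contains non-IUPAC symbols"))
  }
  structure(
    list(name = name, iupac = iupac, max_mismatches = as.integer(max_mismatches)),
    class = "primer_spec"
  )
}

#' @export
print.primer_spec <- function(x, ...) {
  cat("<primer_spec> ", x$name, ": 5'-", x$iupac, "-3' (<=",
      x$max_mismatches, " mismatches)\n", sep = "")
  invisible(x)
}

#' Built-in primers for pmoA and 16S V3-V4 amplicons
#'
#' The standard pmoA primer pairs A189F/mb661R and A189F/A682R, and the 16S
#' rRNA V3-V4 pair 341F/805R, as `primer_spec` objects.
#'
#' @param max_mismatches Mismatches tolerated when matching.
#' @return A `primer_spec`.
#' @export
primer_a189f <- function(max_mismatches = 0L) {
  primer_spec("A189F", "GGNGACTGGGACTTCTGG", max_mismatches)
}

#' @rdname primer_a189f
#' @export
primer_mb661r <- function(max_mismatches = 0L) {
  primer_spec("mb661R", "CCGGMGCAACGTCYTTACC", max_mismatches)
}

#' @rdname primer_a189f
#' @export
primer_a682r <- function(max_mismatches = 0L) {
  primer_spec("A682R", "GAASGCNGAGAAGAASGC", max_mismatches)
}

#' @rdname primer_a189f
#' @export
primer_341f <- function(max_mismatches = 0L) {
  primer_spec("341F", "CCTACGGGNGGCWGCAG", max_mismatches)
}

#' @rdname primer_a189f
#' @export
primer_805r <- function(max_mismatches = 0L) {
  primer_spec("805R", "GACTACHVGGGTATCTAATCC", max_mismatches)
}

# Number of incompatible positions between an IUPAC pattern and an
# equal-length subject window. Positions where bitmasks intersect match.
iupac_mismatches <- function(pattern_bits, subject_bits) {
  sum(bitwAnd(pattern_bits, subject_bits) == 0L)
}

# All start positions (1-based) in `subject` where `pattern` matches with at
# most `max_mm` mismatches under IUPAC compatibility.
iupac_match_positions <- function(pattern, subject, max_mm = 0L) {
  pb <- seq_bits(pattern)
  sb <- seq_bits(subject)
  np <- length(pb)
  ns <- length(sb)
  if (np > ns) return(integer(0))
  starts <- seq_len(ns - np + 1L)
  keep <- vapply(starts, function(s) {
    iupac_mismatches(pb, sb[s:(s + np - 1L)]) <= max_mm
  }, logical(1))
  starts[keep]
}

#' Reading-frame and length expectations for an amplicon class
#'
#' Protein-coding pmoA amplicons trimmed at the standard primers are expected
#' to start with a serine codon (TCG) and end with a tyrosine (TAT, mb661R
#' amplicons) or serine (TCG, A682R amplicons) codon, carry no in-frame stop
#' codon, and fall in a narrow length window. The 16S V3-V4 class is not
#' protein-coding: only the length window (and later the taxonomy filter)
#' applies. The gene-relative codon coordinates (188-190 and 658-660 or
#' 679-681) are carried as metadata; the frame itself is anchored at the
#' first base of the trimmed amplicon.
#'
#' @param name One of `"mb661"`, `"A682"`, `"V3V4"`.
#' @return A `frame_spec` object.
#' @export
#' @examples
#' frame_spec("mb661")
frame_spec <- function(name = c("mb661", "A682", "V3V4")) {
  name <- match.arg(name)
  spec <- switch(name,
    mb661 = list(
      first_codon = "TCG", last_codons = "TAT",
      length_window = c(465L, 474L), frame_checked = TRUE,
      gene_start_codon = c(188L, 190L), gene_end_codon = c(658L, 660L)
    ),
    A682 = list(
      first_codon = "TCG", last_codons = "TCG",
      length_window = c(492L, 495L), frame_checked = TRUE,
      gene_start_codon = c(188L, 190L), gene_end_codon = c(679L, 681L)
    ),
    V3V4 = list(
      first_codon = NA_character_, last_codons = character(0),
      length_window = c(370L, 435L), frame_checked = FALSE,
      gene_start_codon = NULL, gene_end_codon = NULL
    )
  )
  spec$name <- name
  spec$stop_codons <- c("TAA", "TAG", "TGA")
  if (spec$frame_checked &&
      !any(seq(spec$length_window[1], spec$length_window[2]) %% 3L == 0L)) {
    abort("frame_spec length window contains no multiple of 3")
  }
  structure(spec, class = "frame_spec")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat("<frame_spec> ", x$name, ": length [", x$length_window[1], ", ",
      x$length_window[2], "]", sep = "")
  if (x$frame_checked) {
    cat(", first codon ", x$first_codon, ", last codon {",
        paste(x$last_codons, collapse = ","), "}", sep = "")
  } else {
    cat(", no frame check")
  }
  cat("\n")
  invisible(x)
}
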