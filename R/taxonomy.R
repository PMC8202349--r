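# Reference-database construction (primer trimming, dereplication) and
# taxonomic assignment by best global alignment.

#' Trim reference sequences to the amplified region
#'
#' Locates the forward primer site (leftmost IUPAC match) and the
#' reverse-complemented reverse primer site (rightmost match downstream of
#' the forward site) in each entry and emits the between-primers region.
#' Entries lacking either site are dropped with a reason.
#'
#' @param db Tibble with columns `id`, `taxonomy`, `seq` (full-length
#'   reference sequences spanning the amplified region).
#' @param fwd,rev [primer_spec()] objects.
#' @return Tibble `id`, `taxonomy`, `seq` (trimmed; NA when dropped),
#'   `kept` (logical), `reason`.
#' @export
trim_database_to_primers <- function(db, fwd, rev) {
  stopifnot(inherits(fwd, "primer_spec"), inherits(rev, "primer_spec"))
  rc_rev <- dna_revcomp(rev$iupac)
  nf <- nchar(fwd$iupac); nr <- nchar(rc_rev)
  n <- nrow(db)
  seq_out <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- db$seq[i]
    fpos <- iupac_match_positions(fwd$iupac, s, fwd$max_mismatches)
    if (length(fpos) == 0L) {
      reason[i] <- "no_forward_primer"
      next
    }
    f <- fpos[1]
    rpos <- iupac_match_positions(rc_rev, s, rev$max_mismatches)
    rpos <- rpos[rpos >= f + nf]
    if (length(rpos) == 0L) {
      reason[i] <- "no_reverse_primer"
      next
    }
    r <- rpos[length(rpos)]
    seq_out[i] <- substr(s, f + nf, r - 1L)
  }
  tibble(
    id = db$id, taxonomy = db$taxonomy, seq = seq_out,
    kept = is.na(reason), reason = reason
  )
}

#' Dereplicate a reference database
#'
#' Collapses identical trimmed sequences to one entry. When collapsed entries
#' disagree on taxonomy the kept path is their lowest common ancestor (the
#' longest common semicolon-path prefix). Idempotent.
#'
#' @param db Tibble with columns `id`, `taxonomy`, `seq`.
#' @return Tibble `id` (first id of each group), `taxonomy`, `seq`,
#'   `n_collapsed`.
#' @export
dereplicate_database <- function(db) {
  db |>
    dplyr::group_by(.data$seq) |>
    dplyr::summarise(
      id = .data$id[1],
      taxonomy = taxonomy_lca(.data$taxonomy),
      n_collapsed = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("id", "taxonomy", "seq", "n_collapsed") |>
    dplyr::arrange(.data$id)
}

#' Alignment scoring parameters
#'
#' Match/mismatch scores with affine gap penalties for end-to-end
#' (global:global) nucleotide alignment. A gap of length L costs
#' `|gap_open| + L * |gap_extend|`.
#'
#' @param match Match score (default +5).
#' @param mismatch Mismatch score (default -4).
#' @param gap_open Gap opening score (default -10).
#' @param gap_extend Gap extension score per base (default -1).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 5, mismatch = -4, gap_open = -10, gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0,
            gap_open <= gap_extend)
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "alignment_params"
  )
}

.subst_matrix <- function(p) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = p$match, mismatch = p$mismatch, baseOnly = TRUE
  )
}

#' Global pairwise alignment score and identity
#'
#' End-to-end affine-gap alignment of two nucleotide sequences; percent
#' identity is matches over alignment columns (including internal gaps).
#'
#' @param a,b Non-empty nucleotide sequences (character scalars).
#' @param params An [alignment_params()] object.
#' @return Tibble with columns `score` and `identity` (percent).
#' @export
#' @examples
#' global_align("ACGTACGT", "ACGTACGT")
global_align <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) abort("global_align requires non-empty sequences")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .subst_matrix(params),
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend)
  )
  tibble(score = Biostrings::score(al), identity = Biostrings::pid(al, type = "PID1"))
}

#' Assign OTU taxonomy by best global alignment
#'
#' Aligns each OTU representative end-to-end against every database entry;
#' the best score wins. Tied best scores resolve to the lowest common
#' ancestor of the tied entries' taxonomies.
#'
#' @param otus Tibble with columns `otu_id`, `representative`.
#' @param db Reference tibble with columns `id`, `taxonomy`, `seq`.
#' @param params An [alignment_params()] object.
#' @param min_identity Optional identity floor (percent); assignments below
#'   it get taxonomy NA. Default `NULL` (off).
#' @return Tibble `otu_id`, `ref_id` (best entry; first of ties), `identity`,
#'   `taxonomy`.
#' @export
assign_taxonomy <- function(otus, db, params = alignment_params(),
                            min_identity = NULL) {
  if (nrow(db) == 0L) abort("reference database is empty")
  sm <- .subst_matrix(params)
  subj <- Biostrings::DNAStringSet(db$seq)
  out <- vector("list", nrow(otus))
  for (i in seq_len(nrow(otus))) {
    al <- Biostrings::pairwiseAlignment(
      subj, Biostrings::DNAString(otus$representative[i]), type = "global",
      substitutionMatrix = sm,
      gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend)
    )
    sc <- Biostrings::score(al)
    best <- which(sc == max(sc))
    tax <- taxonomy_lca(db$taxonomy[best])
    ident <- Biostrings::pid(al[best[1]], type = "PID1")
    if (!is.null(min_identity) && ident < min_identity) tax <- NA_character_
    out[[i]] <- tibble(
      otu_id = otus$otu_id[i], ref_id = db$id[best[1]],
      identity = ident, taxonomy = tax
    )
  }
  dplyr::bind_rows(out)
}

#' Read and write reference FASTA with taxonomy headers
#'
#' Headers are `id<TAB>taxonomy;semicolon;path`.
#'
#' @param path File path.
#' @param db Tibble with `id`, `taxonomy`, `seq`.
#' @return `read_ref_fasta()` returns a tibble; `write_ref_fasta()` its
#'   input, invisibly.
#' @export
read_ref_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- stringr::str_split_fixed(names(x), "\t", 2)
  tibble(id = hdr[, 1], taxonomy = hdr[, 2], seq = unname(as.character(x)))
}

#' @rdname read_ref_fasta
#' @export
write_ref_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(setNames(db$seq, paste(db$id, db$taxonomy, sep = "\t")))
  Biostrings::writeXStringSet(x, path)
  invisible(db)
}
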