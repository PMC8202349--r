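# Dereplication, chimera screening, single-linkage (swarm-style) clustering,
# reading-frame validation, and OTU-level filters.

#' Dereplicate primer-trimmed reads
#'
#' Collapses identical sequences into amplicons with per-sample counts.
#'
#' @param reads Tibble with columns `sample` and `seq` (one row per read), or
#'   columns `sample`, `seq`, `count` (pre-aggregated).
#' @return Long tibble `seq`, `sample`, `count`, with distinct sequences
#'   ordered by decreasing total count, ties broken lexicographically.
#' @export
dereplicate <- function(reads) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  amp <- reads |>
    dplyr::count(.data$seq, .data$sample, wt = .data$count, name = "count")
  ord <- amp |>
    dplyr::count(.data$seq, wt = .data$count, name = "total") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$seq)
  amp |>
    dplyr::mutate(seq = factor(.data$seq, levels = ord$seq)) |>
    dplyr::arrange(.data$seq, .data$sample) |>
    dplyr::mutate(seq = as.character(.data$seq))
}

#' @rdname dereplicate
#' @param amplicons Long amplicon tibble as returned by `dereplicate()`.
#' @return `amplicon_totals()` returns a tibble `seq`, `total` sorted by
#'   decreasing abundance (ties lexicographic).
#' @export
amplicon_totals <- function(amplicons) {
  amplicons |>
    dplyr::count(.data$seq, wt = .data$count, name = "total") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$seq)
}

# Ungapped identity of two sequences aligned from position 1, over
# max(length) columns (overhang counts as mismatch).
ungapped_identity <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  n <- min(length(ia), length(ib))
  sum(ia[seq_len(n)] == ib[seq_len(n)]) / max(length(ia), length(ib))
}

#' Flag chimeric amplicons
#'
#' A query is flagged as chimeric iff some single-crossover combination of
#' two distinct candidate parents matches it better than any single parent by
#' at least `min_improvement` (identity over the query length, ungapped,
#' prefix aligned at position 1 and suffix aligned at the sequence ends).
#' In de novo mode candidate parents are amplicons at least
#' `min_parent_skew` times more abundant than the query; in reference mode
#' any two database entries qualify.
#'
#' @param amplicons Long amplicon tibble (see [dereplicate()]).
#' @param min_parent_skew De novo parent/query abundance ratio (default 2).
#' @param min_improvement Minimum identity gain of the two-parent model over
#'   the best single parent (default 0.05).
#' @param mode `"denovo"`, `"reference"`, or `"both"` (flag if either mode
#'   flags, mirroring a de novo pass followed by a database pass).
#' @param db Reference tibble with a `seq` column (required unless
#'   `mode = "denovo"`).
#' @return Tibble `seq`, `total`, `chimera` (logical), `improvement`,
#'   sorted by decreasing abundance.
#' @export
detect_chimeras <- function(amplicons, min_parent_skew = 2, min_improvement = 0.05,
                            mode = c("denovo", "reference", "both"), db = NULL) {
  mode <- match.arg(mode)
  stopifnot(min_parent_skew >= 1, min_improvement >= 0)
  if (mode != "denovo" && is.null(db)) {
    abort("reference-mode chimera detection requires `db`")
  }
  tot <- amplicon_totals(amplicons)
  flag <- logical(nrow(tot))
  gain <- numeric(nrow(tot))
  for (i in seq_len(nrow(tot))) {
    parents <- character(0)
    if (mode %in% c("denovo", "both")) {
      keep <- tot$total >= min_parent_skew * tot$total[i] & tot$seq != tot$seq[i]
      parents <- tot$seq[keep]
    }
    if (mode %in% c("reference", "both")) {
      # a db entry identical to the query is a legitimate single parent
      # (identity 100% => not a chimera), so the db is used in full
      parents <- unique(c(parents, db$seq))
    }
    res <- chimera_gain(tot$seq[i], parents)
    gain[i] <- res
    flag[i] <- res >= min_improvement
  }
  dplyr::mutate(tot, chimera = flag, improvement = gain)
}

# Identity gain of the best distinct two-parent crossover model over the best
# single parent, for query `q` against candidate parent sequences.
chimera_gain <- function(q, parents) {
  if (length(parents) < 2L) return(0)
  iq <- utf8ToInt(q)
  n <- length(iq)
  np <- length(parents)
  # prefix[i, p]: matches of q[1..i] vs parent p aligned at the start
  # suffix[k, p]: matches of last k bases of q vs last k of parent p
  pre <- matrix(0L, n, np)
  suf <- matrix(0L, n, np)
  single <- numeric(np)
  for (p in seq_len(np)) {
    ip <- utf8ToInt(parents[p])
    m <- min(n, length(ip))
    eqh <- iq[seq_len(m)] == ip[seq_len(m)]
    pre[, p] <- c(cumsum(eqh), rep(sum(eqh), n - m))
    eqt <- rev(iq)[seq_len(m)] == rev(ip)[seq_len(m)]
    suf[, p] <- c(cumsum(eqt), rep(sum(eqt), n - m))
    single[p] <- sum(eqh) / max(n, length(ip))
  }
  best_single <- max(single)
  best_two <- 0
  for (i in seq_len(n - 1L)) {       # breakpoint after position i
    a <- pre[i, ]
    b <- suf[n - i, ]
    o1 <- order(a, decreasing = TRUE)[seq_len(min(2L, np))]
    o2 <- order(b, decreasing = TRUE)[seq_len(min(2L, np))]
    for (x in o1) for (y in o2) {
      if (x != y) best_two <- max(best_two, (a[x] + b[y]) / n)
    }
  }
  best_two - best_single
}

#' Cluster amplicons into OTUs by iterative single linkage
#'
#' Swarm-style clustering at maximum per-link edit distance `d`: starting
#' from the most abundant unclustered amplicon, a cluster grows by repeatedly
#' absorbing every unclustered amplicon within Levenshtein distance `d` of a
#' current member, so OTUs are the connected components of the distance-`d`
#' graph. The representative is the most abundant member (ties resolved to
#' the lexicographically smallest sequence).
#'
#' @param amplicons Long amplicon tibble (see [dereplicate()]).
#' @param d Maximum edit distance per link (default 1).
#' @return Tibble `otu_id`, `representative`, `seq`, `total`: one row per
#'   member amplicon.
#' @export
cluster_swarm <- function(amplicons, d = 1L) {
  stopifnot(d >= 1L)
  tot <- amplicon_totals(amplicons)
  n <- nrow(tot)
  if (n == 0L) {
    return(tibble(otu_id = character(0), representative = character(0),
                  seq = character(0), total = integer(0)))
  }
  lens <- nchar(tot$seq)
  # candidate links only between length-compatible pairs
  dist_le_d <- function(i, js) {
    js <- js[abs(lens[js] - lens[i]) <= d]
    if (length(js) == 0L) return(integer(0))
    js[adist(tot$seq[i], tot$seq[js])[1, ] <= d]
  }
  cluster <- integer(n)            # 0 = unassigned
  next_id <- 0L
  for (seed in seq_len(n)) {
    if (cluster[seed] != 0L) next
    next_id <- next_id + 1L
    frontier <- seed
    cluster[seed] <- next_id
    while (length(frontier) > 0L) {
      new_frontier <- integer(0)
      for (i in frontier) {
        cand <- which(cluster == 0L)
        hits <- dist_le_d(i, cand)
        if (length(hits) > 0L) {
          cluster[hits] <- next_id
          new_frontier <- c(new_frontier, hits)
        }
      }
      frontier <- new_frontier
    }
  }
  width <- max(3L, nchar(next_id))
  members <- tot |>
    dplyr::mutate(cluster = cluster) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(
      representative = .data$seq[order(-.data$total, .data$seq)][1],
      otu_id = sprintf("OTU_%0*d", width, .data$cluster[1])
    ) |>
    dplyr::ungroup() |>
    dplyr::select("otu_id", "representative", "seq", "total")
  members
}

#' Validate the reading frame of protein-coding amplicons
#'
#' A trimmed amplicon passes iff its length is divisible by three, its first
#' codon equals the expected start codon, its final codon is in the expected
#' set, and no codon in frame 0 is a stop codon. Sequences containing
#' non-ACGT symbols fail with reason `"ambiguous"`. The reason names the
#' first violated rule.
#'
#' @param seqs Character vector of primer-trimmed sequences.
#' @param spec A [frame_spec()] with `frame_checked = TRUE`.
#' @return Tibble `seq`, `valid`, `reason`.
#' @export
validate_reading_frame <- function(seqs, spec) {
  stopifnot(inherits(spec, "frame_spec"))
  if (!spec$frame_checked) {
    abort(paste0("frame_spec '", spec$name, "' is not frame-checked"))
  }
  check_one <- function(s) {
    if (!is_acgt(s)) return("ambiguous")
    n <- nchar(s)
    if (n %% 3L != 0L) return("not divisible by three")
    if (substr(s, 1L, 3L) != spec$first_codon) return("wrong first codon")
    if (!substr(s, n - 2L, n) %in% spec$last_codons) return("wrong last codon")
    codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    if (any(codons %in% spec$stop_codons)) return("stop codon")
    NA_character_
  }
  reason <- vapply(seqs, check_one, character(1), USE.NAMES = FALSE)
  tibble(seq = seqs, valid = is.na(reason), reason = reason)
}

#' Filter OTUs by representative length and taxonomy
#'
#' Retains OTUs whose representative length lies within the closed length
#' window of `spec` and whose taxonomy path contains none of Archaea,
#' chloroplast or mitochondria (case-insensitive).
#'
#' @param otus Tibble with columns `otu_id`, `representative`, `taxonomy`.
#' @param spec A [frame_spec()] supplying the length window.
#' @return Input tibble with logical `retained` and a `reason` column.
#' @export
filter_otus <- function(otus, spec) {
  stopifnot(inherits(spec, "frame_spec"))
  len <- nchar(otus$representative)
  bad_len <- len < spec$length_window[1] | len > spec$length_window[2]
  bad_tax <- stringr::str_detect(
    otus$taxonomy, stringr::regex("archaea|chloroplast|mitochondri", ignore_case = TRUE)
  )
  bad_tax[is.na(bad_tax)] <- FALSE
  dplyr::mutate(otus,
    retained = !bad_len & !bad_tax,
    reason = dplyr::case_when(
      bad_len ~ "length outside window",
      bad_tax ~ "excluded taxonomy",
      TRUE ~ NA_character_
    )
  )
}

#' Build a samples-by-OTUs count table
#'
#' @param members Membership tibble from [cluster_swarm()] (optionally
#'   filtered to retained OTUs).
#' @param amplicons Long amplicon tibble with per-sample counts.
#' @return Wide tibble: `sample` column plus one count column per OTU.
#' @export
build_otu_table <- function(members, amplicons) {
  otu_levels <- unique(members$otu_id)
  amplicons |>
    dplyr::inner_join(members[, c("otu_id", "seq")], by = "seq") |>
    dplyr::count(.data$sample, .data$otu_id, wt = .data$count, name = "count") |>
    dplyr::mutate(otu_id = factor(.data$otu_id, levels = otu_levels)) |>
    tidyr::pivot_wider(
      names_from = "otu_id", values_from = "count",
      values_fill = 0L, names_expand = TRUE
    )
}
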