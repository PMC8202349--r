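#' Run the full amplicon pipeline
#'
#' Chains the pre-clustering hygiene (merge, windowed quality filter, primer
#' trimming), dereplication, chimera screening, reading-frame validation
#' (protein-coding classes only), single-linkage OTU clustering, taxonomic
#' assignment, and the OTU-level length/taxonomy filters into one call,
#' keeping a conservation audit of reads kept and rejected at every stage.
#'
#' @param pairs Paired-read tibble (`read_id`, `sample`, `seq1`, `qual1`,
#'   `seq2`, `qual2`).
#' @param db Reference tibble (`id`, `taxonomy`, `seq`), primer-trimmed and
#'   dereplicated.
#' @param fwd,rev [primer_spec()] objects.
#' @param frame A [frame_spec()] for the amplicon class.
#' @param min_overlap,max_mismatch_density Passed to [merge_pairs()].
#' @param qc_window,qc_min_mean_phred Passed to [filter_reads_quality()].
#' @param chimera_mode,min_parent_skew,min_improvement Passed to
#'   [detect_chimeras()].
#' @param d Swarm link distance, passed to [cluster_swarm()].
#' @param align_params An [alignment_params()] for taxonomic assignment.
#' @return List with `otu_table` (samples x retained OTUs), `otus` (per-OTU
#'   summary with taxonomy and filter status), `members` (amplicon-to-OTU
#'   map), `amplicons` (post-hygiene amplicons), and `log` (tibble of reads
#'   kept/rejected per stage).
#' @export
run_amplicon_pipeline <- function(pairs, db, fwd, rev, frame,
                                  min_overlap = 10L, max_mismatch_density = 0.25,
                                  qc_window = 50L, qc_min_mean_phred = 20,
                                  chimera_mode = "both",
                                  min_parent_skew = 2, min_improvement = 0.05,
                                  d = 1L,
                                  align_params = alignment_params()) {
  log_rows <- list()
  note <- function(stage, kept, rejected) {
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      stage = stage, kept = as.integer(kept), rejected = as.integer(rejected)
    )
  }

  merged <- merge_pairs(pairs, min_overlap, max_mismatch_density)
  merged$sample <- pairs$sample
  note("merge", sum(merged$merged), sum(!merged$merged))
  merged <- merged[merged$merged, ]

  qc <- filter_reads_quality(merged, qc_window, qc_min_mean_phred)
  note("quality_filter", sum(qc$keep), sum(!qc$keep))
  qc <- qc[qc$keep, ]

  trimmed <- trim_primers(qc, fwd, rev)
  note("primer_trim", sum(trimmed$trimmed), sum(!trimmed$trimmed))
  trimmed <- trimmed[trimmed$trimmed, ]

  amplicons <- dereplicate(trimmed[, c("sample", "seq")])

  chim <- detect_chimeras(amplicons, min_parent_skew, min_improvement,
                          mode = chimera_mode, db = db)
  bad_chim <- chim$seq[chim$chimera]
  note("chimera_filter",
       sum(amplicons$count[!amplicons$seq %in% bad_chim]),
       sum(amplicons$count[amplicons$seq %in% bad_chim]))
  amplicons <- amplicons[!amplicons$seq %in% bad_chim, ]

  if (frame$frame_checked) {
    uniq <- unique(amplicons$seq)
    frames <- validate_reading_frame(uniq, frame)
    bad_frame <- frames$seq[!frames$valid]
    note("frame_filter",
         sum(amplicons$count[!amplicons$seq %in% bad_frame]),
         sum(amplicons$count[amplicons$seq %in% bad_frame]))
    amplicons <- amplicons[!amplicons$seq %in% bad_frame, ]
  }

  members <- cluster_swarm(amplicons, d = d)
  otus <- members |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(representative = .data$representative[1],
                     total = sum(.data$total), .groups = "drop")
  assign <- assign_taxonomy(
    dplyr::rename(otus, otu_id = "otu_id"), db, align_params
  )
  otus <- dplyr::left_join(otus, assign, by = "otu_id")
  otus <- filter_otus(otus, frame)
  note("otu_filter",
       sum(otus$total[otus$retained]), sum(otus$total[!otus$retained]))

  retained <- otus[otus$retained, ]
  otu_table <- build_otu_table(
    members[members$otu_id %in% retained$otu_id, ], amplicons
  )
  list(
    otu_table = otu_table, otus = otus, members = members,
    amplicons = amplicons, log = dplyr::bind_rows(log_rows)
  )
}
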