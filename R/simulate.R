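# Synthetic-data generators: reference databases, communities with planted
# bioindicators, paired reads with planted artifacts, and gas time series.
# Every generator is seed-deterministic and returns ground-truth labels so
# downstream tests are parameter-recovery tests.

.codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all[!all %in% c("TAA", "TAG", "TGA")]
})

# Resolve an IUPAC string to one concrete realization (uses the RNG).
resolve_iupac <- function(x) {
  bases <- c("A", "C", "G", "T")
  bits <- seq_bits(x)
  paste(vapply(bits, function(m) {
    opts <- bases[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]
    if (length(opts) == 1L) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# One frame-valid amplicon for a frame_spec (or an unconstrained sequence
# for non-coding classes).
random_amplicon <- function(spec) {
  win <- spec$length_window[1]:spec$length_window[2]
  if (!spec$frame_checked) {
    len <- if (length(win) == 1L) win else sample(win, 1)
    return(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""))
  }
  lens <- win[win %% 3L == 0L]
  if (length(lens) == 0L) abort("length window contains no multiple of 3")
  len <- if (length(lens) == 1L) lens else sample(lens, 1)
  n_codons <- len / 3L
  last <- if (length(spec$last_codons) == 1L) spec$last_codons else sample(spec$last_codons, 1)
  internal <- sample(.codons, n_codons - 2L, replace = TRUE)
  paste(c(spec$first_codon, internal, last), collapse = "")
}

# Mutate third positions of internal codons without breaking frame validity.
mutate_third_positions <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  len <- nchar(seq)
  cand <- seq(6L, len - 3L, by = 3L)
  pos <- sample(cand, min(n_sub, length(cand)))
  chars <- seq_chars(seq)
  for (p in pos) {
    prefix <- paste0(chars[p - 2L], chars[p - 1L])
    allowed <- setdiff(c("A", "C", "G", "T"), chars[p])
    if (prefix == "TA") allowed <- setdiff(allowed, c("A", "G"))
    if (prefix == "TG") allowed <- setdiff(allowed, "A")
    if (length(allowed) > 0L) {
      chars[p] <- if (length(allowed) == 1L) allowed else sample(allowed, 1)
    }
  }
  paste(chars, collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference database
#'
#' Emulates a curated functional-gene reference collection: `n_genera`
#' genus-level consensus amplicons, each with `n_per_genus` strain variants
#' obtained by substituting third codon positions (so every amplicon stays
#' frame-valid), embedded in full-length gene records carrying concrete
#' primer sites and random flanks. Taxonomy paths are
#' `domain;class;order;genus;strain`.
#'
#' @param n_genera,n_per_genus Number of genera and strains per genus.
#' @param frame A [frame_spec()] describing the amplicon class.
#' @param within_genus_divergence Expected substitutions per site between a
#'   strain and its genus consensus (default 0.02).
#' @param fwd,rev [primer_spec()] objects used to build the primer sites.
#' @param flank Length of random flanking sequence on each side of the gene
#'   record (default 30).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return Tibble `id`, `taxonomy`, `seq` (trimmed amplicon), `gene_seq`
#'   (full record). The concrete primer realizations are attached as
#'   attributes `fwd_site` and `rev_site`.
#' @export
sim_reference_db <- function(n_genera = 3, n_per_genus = 2,
                             frame = frame_spec("mb661"),
                             within_genus_divergence = 0.02,
                             fwd = primer_a189f(), rev = primer_mb661r(),
                             flank = 30L, seed = 1L) {
  stopifnot(n_genera >= 1, n_per_genus >= 1, within_genus_divergence >= 0)
  set.seed(seed)
  fwd_site <- resolve_iupac(fwd$iupac)
  rev_site <- resolve_iupac(rev$iupac)
  rc_rev <- dna_revcomp(rev_site)
  rows <- vector("list", n_genera * n_per_genus)
  k <- 0L
  for (g in seq_len(n_genera)) {
    consensus <- random_amplicon(frame)
    genus <- sprintf("Genus%02d", g)
    for (s in seq_len(n_per_genus)) {
      amp <- if (s == 1L) consensus else {
        n_sub <- stats::rbinom(1L, nchar(consensus), within_genus_divergence)
        mutate_third_positions(consensus, n_sub)
      }
      k <- k + 1L
      rows[[k]] <- tibble(
        id = sprintf("G%02d_S%02d", g, s),
        taxonomy = paste("Bacteria", "Gammaproteobacteria", "Methylococcales",
                         genus, sprintf("%s_str%02d", genus, s), sep = ";"),
        seq = amp,
        gene_seq = paste0(.random_dna(flank), fwd_site, amp, rc_rev,
                          .random_dna(flank))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fwd_site") <- fwd_site
  attr(out, "rev_site") <- rev_site
  out
}

#' Design a synthetic community experiment
#'
#' Describes a factorial field design (sites x treatments x dates x
#' replicates) with `n_background_otus` unstructured OTUs plus one planted
#' bioindicator OTU per row of `planted`, whose expected abundance is
#' multiplied by `fold_change` in its favored treatment only.
#'
#' @param sites,treatments,dates Factor level labels.
#' @param replicates_per_cell Replicates per site x treatment x date cell.
#' @param n_background_otus Number of unstructured OTUs.
#' @param planted Tibble with columns `favored_treatment` and `fold_change`
#'   (all > 1); planted OTUs are appended after the background OTUs. May
#'   have zero rows.
#' @param sequencing_depth Reads per sample (> 0).
#' @param overdispersion Log-scale SD of the per-sample abundance noise.
#' @param seed Integer seed.
#' @return A `community_design` list; the planted tibble gains an
#'   `otu_index` column.
#' @export
community_design <- function(sites = c("SV1", "SV2"),
                             treatments = c("grazed", "exclosed"),
                             dates = c("summer2015", "spring2016"),
                             replicates_per_cell = 3,
                             n_background_otus = 30,
                             planted = tibble(favored_treatment = character(0),
                                              fold_change = numeric(0)),
                             sequencing_depth = 2000,
                             overdispersion = 0.5,
                             seed = 1L) {
  stopifnot(replicates_per_cell >= 0, n_background_otus >= 0,
            sequencing_depth > 0, overdispersion > 0)
  if (nrow(planted) > 0) {
    stopifnot(all(planted$fold_change > 1),
              all(planted$favored_treatment %in% treatments))
  }
  planted$otu_index <- n_background_otus + seq_len(nrow(planted))
  structure(list(
    sites = sites, treatments = treatments, dates = dates,
    replicates_per_cell = replicates_per_cell,
    n_background_otus = n_background_otus, planted = planted,
    n_otus = n_background_otus + nrow(planted),
    sequencing_depth = sequencing_depth,
    overdispersion = overdispersion, seed = seed
  ), class = "community_design")
}

#' Simulate community counts with planted treatment effects
#'
#' OTU baseline relative abundances are log-normal (a standard
#' rank-abundance model); each sample draws multinomial counts at the
#' design's sequencing depth from the baseline multiplied by per-sample
#' log-normal noise and, for planted OTUs in their favored treatment, the
#' fold-change. Row sums equal the sequencing depth exactly.
#'
#' @param design A [community_design()].
#' @return List with `counts` (tibble: `sample` + one column per OTU),
#'   `metadata` (tibble: `sample`, `site`, `treatment`, `date`, `replicate`,
#'   `ch4_rate`), and `truth` (tibble: `otu`, `planted`,
#'   `favored_treatment`, `fold_change`).
#' @export
sim_community_counts <- function(design) {
  stopifnot(inherits(design, "community_design"))
  set.seed(design$seed)
  grid <- expand.grid(
    replicate = seq_len(design$replicates_per_cell),
    date = design$dates, treatment = design$treatments, site = design$sites,
    stringsAsFactors = FALSE
  )
  n_otus <- design$n_otus
  otu_ids <- sprintf("otu%03d", seq_len(n_otus))
  base <- rlnorm(n_otus, meanlog = 0, sdlog = 1)
  fold <- function(treatment) {
    f <- rep(1, n_otus)
    if (nrow(design$planted) > 0) {
      hit <- design$planted$favored_treatment == treatment
      f[design$planted$otu_index[hit]] <- design$planted$fold_change[hit]
    }
    f
  }
  n_samples <- nrow(grid)
  counts <- matrix(0L, n_samples, n_otus, dimnames = list(NULL, otu_ids))
  for (i in seq_len(n_samples)) {
    lambda <- base * fold(grid$treatment[i]) *
      exp(rnorm(n_otus, 0, design$overdispersion))
    counts[i, ] <- rmultinom(1, design$sequencing_depth, lambda)[, 1]
  }
  sample_id <- sprintf("%s_%s_%s_r%d", grid$site, grid$treatment,
                       grid$date, grid$replicate)
  truth <- tibble(
    otu = otu_ids,
    planted = seq_len(n_otus) %in% design$planted$otu_index,
    favored_treatment = NA_character_, fold_change = 1
  )
  if (nrow(design$planted) > 0) {
    truth$favored_treatment[design$planted$otu_index] <- design$planted$favored_treatment
    truth$fold_change[design$planted$otu_index] <- design$planted$fold_change
  }
  list(
    counts = dplyr::bind_cols(tibble(sample = sample_id), as_tibble(counts)),
    metadata = tibble(
      sample = sample_id, site = grid$site, treatment = grid$treatment,
      date = grid$date, replicate = grid$replicate,
      ch4_rate = rlnorm(n_samples, log(50), 0.4)
    ),
    truth = truth
  )
}

#' Read-simulation parameters
#'
#' @param read_length Read length in nt.
#' @param target_overlap Minimum overlap of the two mates in nt
#'   (`read_length > target_overlap > 0`).
#' @param substitution_rate Per-base sequencing error probability.
#' @param quality_profile Numeric vector of per-position mean phred scores
#'   (length `read_length`), or `NULL` for a MiSeq-like profile decaying
#'   toward the read end.
#' @param quality_jitter SD of the Gaussian jitter added to the profile
#'   (scores clamped to \[2, 40\]).
#' @param chimera_rate Fraction of fragments replaced by two-parent
#'   crossovers.
#' @param frameshift_rate Fraction of fragments carrying a 1-nt indel.
#' @param fwd,rev [primer_spec()] objects.
#' @param seed Integer seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 280L, target_overlap = 30L,
                            substitution_rate = 0, quality_profile = NULL,
                            quality_jitter = 3, chimera_rate = 0,
                            frameshift_rate = 0,
                            fwd = primer_a189f(), rev = primer_mb661r(),
                            seed = 1L) {
  stopifnot(read_length > target_overlap, target_overlap > 0,
            substitution_rate >= 0, substitution_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            frameshift_rate >= 0, frameshift_rate <= 1,
            chimera_rate + frameshift_rate <= 1)
  if (is.null(quality_profile)) {
    pos <- seq_len(read_length)
    quality_profile <- 38 - 10 * ((pos - 1) / (read_length - 1))^2
  }
  stopifnot(length(quality_profile) == read_length)
  structure(list(
    read_length = as.integer(read_length),
    target_overlap = as.integer(target_overlap),
    substitution_rate = substitution_rate,
    quality_profile = quality_profile, quality_jitter = quality_jitter,
    chimera_rate = chimera_rate, frameshift_rate = frameshift_rate,
    fwd = fwd, rev = rev, seed = seed
  ), class = "read_sim_params")
}

.mutate_bases <- function(chars, idx) {
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1)
  }
  chars
}

.sim_qual <- function(params) {
  q <- round(params$quality_profile +
               rnorm(params$read_length, 0, params$quality_jitter))
  phred_string(pmin(40L, pmax(2L, as.integer(q))))
}

#' Simulate paired-end amplicon reads with planted artifacts
#'
#' Each fragment is the concrete forward primer site, an amplicon, and the
#' reverse-complemented reverse primer site; mates of `read_length` nt are
#' taken from both fragment ends so they overlap. A fraction `chimera_rate`
#' of fragments are single-crossover two-parent chimeras (breakpoint uniform
#' over the central 10-90% of the amplicon, so both parents contribute a
#' detectable block); a fraction `frameshift_rate` carry a 1-nt insertion or
#' deletion. Sequencing substitutions are applied per read base.
#'
#' @param counts Community count tibble (`sample` column + one column per
#'   OTU); columns correspond positionally to the rows of `refdb`.
#' @param refdb Reference tibble from [sim_reference_db()] (uses its
#'   `fwd_site`/`rev_site` attributes when present).
#' @param params A [read_sim_params()].
#' @return List with `reads` (tibble `read_id`, `sample`, `seq1`, `qual1`,
#'   `seq2`, `qual2`) and `truth` (tibble `read_id`, `sample`, `ref_id`,
#'   `class`, `parent2`, `breakpoint`).
#' @export
sim_paired_reads <- function(counts, refdb, params = read_sim_params()) {
  stopifnot(inherits(params, "read_sim_params"))
  otu_cols <- setdiff(names(counts), "sample")
  if (length(otu_cols) != nrow(refdb)) {
    abort("count columns must correspond to reference entries")
  }
  set.seed(params$seed)
  fwd_site <- attr(refdb, "fwd_site") %||% resolve_iupac(params$fwd$iupac)
  rev_site <- attr(refdb, "rev_site") %||% resolve_iupac(params$rev$iupac)
  rc_rev <- dna_revcomp(rev_site)
  rl <- params$read_length

  read_rows <- list()
  truth_rows <- list()
  read_no <- 0L
  for (s in seq_len(nrow(counts))) {
    samp <- counts$sample[s]
    cvec <- as.numeric(counts[s, otu_cols])
    present <- which(cvec > 0)
    for (o in present) {
      for (r in seq_len(cvec[o])) {
        read_no <- read_no + 1L
        amp <- refdb$seq[o]
        cls <- "normal"; parent2 <- NA_character_; bp <- NA_integer_
        u <- runif(1)
        if (u < params$chimera_rate && length(present) >= 2L) {
          cls <- "chimera"
          others <- setdiff(present, o)
          o2 <- if (length(others) == 1L) others else {
            sample(others, 1, prob = cvec[others])
          }
          amp2 <- refdb$seq[o2]
          lmin <- min(nchar(amp), nchar(amp2))
          lo <- max(2L, ceiling(0.1 * lmin))
          hi <- min(lmin - 1L, floor(0.9 * lmin))
          bp <- if (hi <= lo) lo else sample(lo:hi, 1)
          amp <- paste0(substr(amp, 1L, bp), substr(amp2, bp + 1L, nchar(amp2)))
          parent2 <- refdb$id[o2]
        } else if (u < params$chimera_rate + params$frameshift_rate) {
          cls <- "frameshift"
          pos <- sample(2L:(nchar(amp) - 1L), 1)
          amp <- if (runif(1) < 0.5) {
            paste0(substr(amp, 1L, pos - 1L), substr(amp, pos + 1L, nchar(amp)))
          } else {
            paste0(substr(amp, 1L, pos),
                   sample(c("A", "C", "G", "T"), 1),
                   substr(amp, pos + 1L, nchar(amp)))
          }
        }
        frag <- paste0(fwd_site, amp, rc_rev)
        flen <- nchar(frag)
        if (rl > flen) abort("read_length longer than fragment")
        if (2L * rl - flen < params$target_overlap) {
          abort("reads too short to reach the target overlap")
        }
        r1 <- seq_chars(substr(frag, 1L, rl))
        r2 <- seq_chars(dna_revcomp(substr(frag, flen - rl + 1L, flen)))
        if (params$substitution_rate > 0) {
          r1 <- .mutate_bases(r1, which(runif(rl) < params$substitution_rate))
          r2 <- .mutate_bases(r2, which(runif(rl) < params$substitution_rate))
        }
        rid <- sprintf("read%06d", read_no)
        read_rows[[read_no]] <- tibble(
          read_id = rid, sample = samp,
          seq1 = paste(r1, collapse = ""), qual1 = .sim_qual(params),
          seq2 = paste(r2, collapse = ""), qual2 = .sim_qual(params)
        )
        truth_rows[[read_no]] <- tibble(
          read_id = rid, sample = samp, ref_id = refdb$id[o],
          class = cls, parent2 = parent2, breakpoint = bp
        )
      }
    }
  }
  list(reads = dplyr::bind_rows(read_rows), truth = dplyr::bind_rows(truth_rows))
}

#' Simulate a closed-vial gas consumption time series
#'
#' Headspace CH4 mass declines linearly, `mass(t) = initial_mass -
#' consumption_rate * t + noise`, clipped at zero. When a
#' [microcosm_spec()] is supplied the equivalent headspace volume fraction
#' is included (inverse ideal gas law at the incubation temperature).
#'
#' @param initial_mass Initial headspace CH4 mass, ug.
#' @param consumption_rate Consumption, ug per hour.
#' @param timepoints Strictly increasing sampling times, hours.
#' @param noise_sd Gaussian measurement noise SD, ug (>= 0).
#' @param seed Integer seed.
#' @param spec Optional [microcosm_spec()] for the fraction conversion.
#' @param constants A [gas_constants()] object.
#' @return Tibble `time_h`, `mass_ug` (and `ch4_fraction` when `spec` is
#'   given).
#' @export
sim_gas_series <- function(initial_mass, consumption_rate,
                           timepoints = c(0, 11, 22, 34, 45), noise_sd = 0,
                           seed = 1L, spec = NULL,
                           constants = gas_constants()) {
  stopifnot(noise_sd >= 0, length(timepoints) >= 2)
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  set.seed(seed)
  mass <- initial_mass - consumption_rate * timepoints +
    rnorm(length(timepoints), 0, noise_sd)
  mass <- pmax(mass, 0)
  out <- tibble(time_h = timepoints, mass_ug = mass)
  if (!is.null(spec)) {
    mol_per_frac <- spec$pressure * spec$headspace_volume / 1000 /
      (constants$R * (spec$incubation_temp + 273.15))
    out$ch4_fraction <- mass / (mol_per_frac * constants$m_ch4 * 1e6)
  }
  out
}
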