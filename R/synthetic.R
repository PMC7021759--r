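#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic H3.3 peak landscape
#'
#' Plants non-overlapping peaks on a small artificial genome, each carrying a
#' true occupancy label across the three genotype groups
#' (`ATRX`-mutant, `MYCN`-amplified, wild-type):
#' \describe{
#'   \item{C}{constitutive -- present in all three groups;}
#'   \item{E}{enriched -- present only in ATRX;}
#'   \item{D}{depleted -- absent in ATRX, present in MYCN and WT;}
#'   \item{O}{overlapping -- present in ATRX plus exactly one of MYCN/WT.}
#' }
#' Each peak also carries planted G-quadruplex and R-loop-forming-sequence
#' flags (RLFS only among G4-flagged peaks, matching the conditional
#' reporting convention) and, for a fraction of peaks, a gene TSS at the
#' peak midpoint so promoter/enhancer location calls can be exercised.
#'
#' @param n_per_label named integer vector of planted peak counts per label.
#' @param genome_sizes named numeric vector of sequence lengths (bp).
#' @param peak_width planted peak width (bp).
#' @param min_gap minimum bp between planted peaks, so that replicate
#'   jitter and low-confidence padding never bridge two distinct peaks.
#' @param g4_fraction probability that a planted peak carries a G4 motif.
#' @param rlfs_given_g4 conditional probability of an RLFS given G4.
#' @param promoter_fraction fraction of planted peaks given a TSS at their
#'   midpoint.
#' @param replicates samples per genotype group.
#' @param seed integer seed; all downstream simulation is deterministic
#'   given the truth.
#' @return A `landscape_truth` list with the planted peak table
#'   (`tibble`: seq, start, end, label, g4, rlfs, o_partner, promoter),
#'   the genome, group design and the generator parameters.
#' @export
landscape_truth <- function(n_per_label = c(C = 10, E = 10, D = 10, O = 10),
                            genome_sizes = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                            peak_width = 600,
                            min_gap = 1000,
                            g4_fraction = 0.35,
                            rlfs_given_g4 = 0.70,
                            promoter_fraction = 0.3,
                            replicates = 2,
                            seed = 1) {
  stopifnot(all(c("C", "E", "D", "O") %in% names(n_per_label)),
            all(n_per_label >= 0), peak_width >= 1,
            g4_fraction >= 0, g4_fraction <= 1,
            rlfs_given_g4 >= 0, rlfs_given_g4 <= 1,
            replicates >= 1)
  n <- sum(n_per_label)
  if (n * (peak_width + min_gap) > sum(genome_sizes))
    stop("genome too small to place ", n, " planted peaks of width ",
         peak_width, " with gap ", min_gap)
  with_seed(seed, {
    placed <- .place_nonoverlapping(n, peak_width, genome_sizes, min_gap)
    labels <- rep(names(n_per_label), n_per_label)
    labels <- sample(labels)  # interleave labels across the genome
    o_partner <- rep(NA_character_, n)
    o_partner[labels == "O"] <- sample(c("MYCN", "WT"), sum(labels == "O"),
                                       replace = TRUE)
    g4 <- stats::runif(n) < g4_fraction
    rlfs <- g4 & (stats::runif(n) < rlfs_given_g4)
    promoter <- stats::runif(n) < promoter_fraction
    peaks <- tibble::tibble(
      seq = placed$seq, start = placed$start, end = placed$end,
      label = labels, g4 = g4, rlfs = rlfs,
      o_partner = o_partner, promoter = promoter
    )
    structure(list(
      planted_peaks = peaks,
      genome_sizes = genome_sizes,
      groups = c("ATRX", "MYCN", "WT"),
      replicates = replicates,
      peak_width = peak_width,
      min_gap = min_gap,
      g4_fraction = g4_fraction,
      rlfs_given_g4 = rlfs_given_g4,
      promoter_fraction = promoter_fraction,
      seed = seed
    ), class = "landscape_truth")
  })
}

# Rejection-sample n non-overlapping intervals of fixed width.
.place_nonoverlapping <- function(n, width, genome_sizes, min_gap) {
  seqs <- names(genome_sizes)
  starts <- integer(0); ends <- integer(0); on_seq <- character(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n)
      stop("genome too small to place requested peaks (placement failure)")
    s <- sample(seqs, 1, prob = genome_sizes / sum(genome_sizes))
    pos <- floor(stats::runif(1, 0, genome_sizes[[s]] - width))
    same <- on_seq == s
    if (any(same & starts < pos + width + min_gap & ends + min_gap > pos))
      next
    starts <- c(starts, pos); ends <- c(ends, pos + width)
    on_seq <- c(on_seq, s)
  }
  ord <- order(on_seq, starts)
  list(seq = on_seq[ord], start = starts[ord], end = ends[ord])
}

#' Is a planted peak present in a given genotype group?
#'
#' @param label planted label (`C`, `E`, `D`, `O`).
#' @param o_partner the non-ATRX group sharing an O peak.
#' @param group one of `ATRX`, `MYCN`, `WT`.
#' @return Logical vector.
#' @keywords internal
planted_presence <- function(label, o_partner, group) {
  ifelse(label == "C", TRUE,
  ifelse(label == "E", group == "ATRX",
  ifelse(label == "D", group != "ATRX",
         group == "ATRX" | group == o_partner)))
}

#' Simulate a full peak-landscape input bundle
#'
#' Generates, for every sample of the 3-group design, high- and
#' low-confidence peak calls, paired-end fragment intervals, and an 18-state
#' segmentation; plus shared G4 and RLFS tracks and a TSS/gene table.  All
#' pieces follow from the planted truth:
#' \itemize{
#'   \item high-confidence peaks appear at planted peaks present in the
#'     sample's group, jittered by at most `jitter` bp per edge;
#'   \item low-confidence peaks are the high-confidence peaks padded by
#'     `low_pad` bp plus spurious low-only peaks at rate `low_only_rate`
#'     per bp;
#'   \item fragments are drawn around present peaks (`Poisson(enrichment)`
#'     per peak, clipped-normal lengths spanning the 2000 bp counting
#'     cutoff) over a uniform background of `noise_rate` fragments per kbp;
#'   \item segmentations assign an active-class state over present peaks
#'     (promoter peaks get a promoter-active state, distal peaks an
#'     enhancer-class state) and an inactive heterochromatic state over
#'     planted peaks absent from the sample, on a quiescent background.
#' }
#'
#' @param truth a [landscape_truth()] object.
#' @param jitter maximum per-edge peak-call jitter (bp).
#' @param low_pad padding of low-confidence peaks around high-confidence
#'   ones (bp).
#' @param low_only_rate expected spurious low-only peaks per bp.
#' @param enrichment expected fragments per present planted peak per sample.
#' @param noise_rate background fragments per kbp per sample.
#' @param fragment_mean,fragment_sd,fragment_clip clipped-normal fragment
#'   length model (bp); the defaults straddle the 2000 bp size filter so the
#'   filter removes a visible fraction.
#' @param g4_width,rlfs_width width of planted track intervals (bp).
#' @param n_background_g4,n_background_rlfs track intervals placed away from
#'   planted peaks (so planted overlap fractions stay interpretable).
#' @param n_background_genes genes with TSS placed away from planted peaks.
#' @param states named list giving the segmentation states used for
#'   promoter-active, enhancer-active, absent and background territory.
#' @return A `landscape_bundle` list: `samples` (per sample: `id`, `group`,
#'   `high`, `low`, `fragments`, `segmentation` as `GRanges`), `g4`, `rlfs`
#'   (`GRanges`), `tss` (tibble), `state_classes`, and the `truth`.
#' @export
simulate_peak_landscape <- function(truth,
                                    jitter = 25,
                                    low_pad = 100,
                                    low_only_rate = 2e-5,
                                    enrichment = 40,
                                    noise_rate = 0.2,
                                    fragment_mean = 250,
                                    fragment_sd = 300,
                                    fragment_clip = c(50, 4000),
                                    g4_width = 100,
                                    rlfs_width = 150,
                                    n_background_g4 = 200,
                                    n_background_rlfs = 200,
                                    n_background_genes = 100,
                                    states = list(promoter_active = 2L,
                                                  enhancer_active = 6L,
                                                  absent = 16L,
                                                  background = 9L)) {
  stopifnot(inherits(truth, "landscape_truth"))
  pk <- truth$planted_peaks
  genome <- truth$genome_sizes
  with_seed(truth$seed + 1L, {
    samples <- list()
    for (g in truth$groups) {
      present <- planted_presence(pk$label, pk$o_partner, g)
      for (r in seq_len(truth$replicates)) {
        id <- paste0(g, "_", r)
        samples[[id]] <- .simulate_sample(
          id, g, pk, present, genome, jitter, low_pad, low_only_rate,
          enrichment, noise_rate, fragment_mean, fragment_sd, fragment_clip,
          truth$peak_width, states)
      }
    }
    g4 <- .simulate_track(pk[pk$g4, ], genome, g4_width, n_background_g4,
                          avoid = pk)
    rlfs <- .simulate_track(pk[pk$rlfs, ], genome, rlfs_width,
                            n_background_rlfs, avoid = pk)
    tss <- .simulate_tss(pk, genome, n_background_genes)
    structure(list(
      samples = samples,
      g4 = g4, rlfs = rlfs, tss = tss,
      state_classes = default_state_classes(),
      truth = truth
    ), class = "landscape_bundle")
  })
}

.jitter_peaks <- function(pk_sub, genome, jitter) {
  n <- nrow(pk_sub)
  if (!n) return(interval_set(character(0), integer(0), integer(0)))
  js <- if (jitter > 0) sample(-jitter:jitter, n, replace = TRUE) else integer(n)
  je <- if (jitter > 0) sample(-jitter:jitter, n, replace = TRUE) else integer(n)
  start <- pmax(0, pk_sub$start + js)
  end <- pmin(genome[pk_sub$seq], pk_sub$end + je)
  end <- pmax(end, start + 1)
  interval_set(pk_sub$seq, start, end)
}

.simulate_sample <- function(id, group, pk, present, genome, jitter, low_pad,
                             low_only_rate, enrichment, noise_rate,
                             fragment_mean, fragment_sd, fragment_clip,
                             peak_width, states) {
  high <- .jitter_peaks(pk[present, ], genome, jitter)
  # low-confidence calls: padded high calls plus spurious low-only peaks
  lo_start <- pmax(0, interval_start(high) - low_pad)
  lo_end <- pmin(genome[as.character(GenomicRanges::seqnames(high))],
                 interval_end(high) + low_pad)
  low <- interval_set(as.character(GenomicRanges::seqnames(high)),
                      lo_start, lo_end)
  n_extra <- stats::rpois(1, low_only_rate * sum(genome))
  if (n_extra > 0) {
    seqs <- sample(names(genome), n_extra, replace = TRUE,
                   prob = genome / sum(genome))
    st <- floor(stats::runif(n_extra, 0, genome[seqs] - peak_width))
    low <- c(low, interval_set(seqs, st, st + peak_width))
  }
  low <- GenomicRanges::sort(low)

  fragments <- .simulate_fragments(pk[present, ], genome, enrichment,
                                   noise_rate, fragment_mean, fragment_sd,
                                   fragment_clip)
  seg <- .simulate_segmentation(pk, present, genome, states)
  list(id = id, group = group, high = high, low = low,
       fragments = fragments, segmentation = seg)
}

.clip_lengths <- function(n, mean, sd, clip) {
  len <- stats::rnorm(n, mean, sd)
  pmin(pmax(round(len), clip[1]), clip[2])
}

.simulate_fragments <- function(pk_present, genome, enrichment, noise_rate,
                                fragment_mean, fragment_sd, fragment_clip) {
  seqs <- character(0); starts <- numeric(0); ends <- numeric(0)
  if (nrow(pk_present) && enrichment > 0) {
    n_per <- stats::rpois(nrow(pk_present), enrichment)
    idx <- rep(seq_len(nrow(pk_present)), n_per)
    if (length(idx)) {
      centers <- floor(stats::runif(length(idx), pk_present$start[idx],
                                    pk_present$end[idx]))
      len <- .clip_lengths(length(idx), fragment_mean, fragment_sd,
                           fragment_clip)
      seqs <- pk_present$seq[idx]
      starts <- pmax(0, centers - floor(len / 2))
      ends <- pmin(genome[seqs], centers + ceiling(len / 2))
    }
  }
  n_bg <- stats::rpois(1, noise_rate * sum(genome) / 1000)
  if (n_bg > 0) {
    bseq <- sample(names(genome), n_bg, replace = TRUE,
                   prob = genome / sum(genome))
    bcen <- floor(stats::runif(n_bg, 0, genome[bseq]))
    blen <- .clip_lengths(n_bg, fragment_mean, fragment_sd, fragment_clip)
    seqs <- c(seqs, bseq)
    starts <- c(starts, pmax(0, bcen - floor(blen / 2)))
    ends <- c(ends, pmin(genome[bseq], bcen + ceiling(blen / 2)))
  }
  keep <- ends > starts
  GenomicRanges::sort(interval_set(seqs[keep], starts[keep], ends[keep]))
}

.simulate_segmentation <- function(pk, present, genome, states) {
  state_at_peak <- ifelse(present,
                          ifelse(pk$promoter, states$promoter_active,
                                 states$enhancer_active),
                          states$absent)
  peak_gr <- interval_set(pk$seq, pk$start, pk$end, state = state_at_peak)
  genome_gr <- interval_set(names(genome), rep(0, length(genome)), genome)
  gaps <- GenomicRanges::setdiff(genome_gr, peak_gr, ignore.strand = TRUE)
  S4Vectors::mcols(gaps)$state <- states$background
  GenomicRanges::sort(c(peak_gr, gaps))
}

.simulate_track <- function(pk_flagged, genome, width, n_background, avoid) {
  seqs <- character(0); starts <- numeric(0); ends <- numeric(0)
  if (nrow(pk_flagged)) {
    centers <- floor((pk_flagged$start + pk_flagged$end) / 2)
    seqs <- pk_flagged$seq
    starts <- pmax(0, centers - floor(width / 2))
    ends <- pmin(genome[seqs], centers + ceiling(width / 2))
  }
  avoid_gr <- interval_set(avoid$seq, avoid$start, avoid$end)
  placed <- 0L; tries <- 0L
  while (placed < n_background && tries < 50L * max(n_background, 1L)) {
    tries <- tries + 1L
    s <- sample(names(genome), 1, prob = genome / sum(genome))
    pos <- floor(stats::runif(1, 0, genome[[s]] - width))
    cand <- interval_set(s, pos, pos + width)
    if (any(overlap_query(cand, avoid_gr)$hit)) next
    seqs <- c(seqs, s); starts <- c(starts, pos); ends <- c(ends, pos + width)
    placed <- placed + 1L
  }
  GenomicRanges::sort(interval_set(seqs, starts, ends))
}

.simulate_tss <- function(pk, genome, n_background_genes) {
  prom <- pk[pk$promoter, ]
  genes <- tibble::tibble(
    gene_id = character(0), seq = character(0), tss = numeric(0),
    strand = character(0), fpkm = numeric(0)
  )
  if (nrow(prom)) {
    genes <- tibble::tibble(
      gene_id = sprintf("gene_pk%04d", which(pk$promoter)),
      seq = prom$seq,
      tss = floor((prom$start + prom$end) / 2),
      strand = sample(c("+", "-"), nrow(prom), replace = TRUE),
      fpkm = stats::rlnorm(nrow(prom), 2, 1)
    )
  }
  pk_gr <- interval_set(pk$seq, pk$start, pk$end)
  placed <- 0L; tries <- 0L
  bg <- list(seq = character(0), tss = numeric(0))
  while (placed < n_background_genes && tries < 50L * max(n_background_genes, 1L)) {
    tries <- tries + 1L
    s <- sample(names(genome), 1, prob = genome / sum(genome))
    pos <- floor(stats::runif(1, 3000, genome[[s]] - 3000))
    cand <- interval_set(s, pos - 2000, pos + 2000)
    if (any(overlap_query(cand, pk_gr)$hit)) next
    bg$seq <- c(bg$seq, s); bg$tss <- c(bg$tss, pos)
    placed <- placed + 1L
  }
  if (placed) {
    genes <- rbind(genes, tibble::tibble(
      gene_id = sprintf("gene_bg%04d", seq_len(placed)),
      seq = bg$seq, tss = bg$tss,
      strand = sample(c("+", "-"), placed, replace = TRUE),
      fpkm = stats::rlnorm(placed, 2, 1)
    ))
  }
  genes
}

#' Default functional classes for the 18 segmentation states
#'
#' States 1--4 are active euchromatic (promoter/transcription), 5--7
#' enhancer, 13 strongly transcribed gene body, 15--17 inactive
#' heterochromatic, 18 CTCF; everything else is "other".
#'
#' @return Named character vector, one class per state `"1"`..`"18"`.
#' @export
default_state_classes <- function() {
  cls <- rep("other", 18)
  cls[1:4] <- "active"
  cls[5:7] <- "enhancer"
  cls[15:17] <- "inactive"
  cls[18] <- "ctcf"
  names(cls) <- as.character(1:18)
  cls
}

#' Write a simulated landscape bundle to plain-text files
#'
#' Emits standard BED files for per-sample high/low peak calls, fragments
#' and segmentations (4th column `E<state>`), BED for the G4 and RLFS
#' tracks, a TSV TSS table and a TSV truth table.
#'
#' @param bundle a [simulate_peak_landscape()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in bundle$samples) {
    write_bed(s$high, file.path(dir, paste0(s$id, "_high.bed")))
    write_bed(s$low, file.path(dir, paste0(s$id, "_low.bed")))
    write_bed(s$fragments, file.path(dir, paste0(s$id, "_fragments.bed")))
    seg <- s$segmentation
    df <- data.frame(
      seq = as.character(GenomicRanges::seqnames(seg)),
      start = interval_start(seg), end = interval_end(seg),
      state = paste0("E", S4Vectors::mcols(seg)$state)
    )
    utils::write.table(df, file.path(dir, paste0(s$id, "_segmentation.bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_bed(bundle$g4, file.path(dir, "g4_motifs.bed"))
  write_bed(bundle$rlfs, file.path(dir, "rlfs.bed"))
  utils::write.table(bundle$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$planted_peaks, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Specification of a synthetic patient cohort
#'
#' @param strata a data frame with columns `stratum`, `n_total`, `n_mutant`.
#' @param seed integer seed controlling which patients are mutant.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(strata, seed = 1) {
  strata <- tibble::as_tibble(strata)
  stopifnot(all(c("stratum", "n_total", "n_mutant") %in% names(strata)))
  if (any(strata$n_mutant < 0 | strata$n_mutant > strata$n_total))
    stop("need 0 <= n_mutant <= n_total in every stratum")
  structure(list(strata = strata, seed = seed), class = "cohort_spec")
}

#' Simulate a patient cohort with exact per-stratum mutation counts
#'
#' Per-stratum totals and mutant counts equal the requested counts exactly;
#' only the assignment of which patients are mutant (and the row order
#' within strata) is randomized by the seed.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with one row per patient: `patient_id`, `stratum`,
#'   `mutant` (logical).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$strata)), function(i) {
      n <- spec$strata$n_total[i]
      k <- spec$strata$n_mutant[i]
      mut <- rep(FALSE, n)
      if (k > 0) mut[sample.int(n, k)] <- TRUE
      tibble::tibble(
        patient_id = sprintf("%s_%04d", gsub("[^A-Za-z0-9]+", "_",
                                             spec$strata$stratum[i]),
                             seq_len(n)),
        stratum = spec$strata$stratum[i],
        mutant = mut
      )
    })
    do.call(rbind, rows)
  })
}

#' ATRX mutation counts per clinical classification in the study cohort
#'
#' The packaged fixture for the 473-patient COG neuroblastoma cohort:
#' per-classification patient totals and ATRX-mutant counts, verbatim.
#' Because each classification is tallied over the patients for whom that
#' classifier was applied, totals differ between classifications.
#'
#' @return A tibble with columns `classification`, `level`, `n`,
#'   `n_mutant`, and `test` (the association test that reproduces the
#'   cohort analysis for that classification: `"fisher"` or
#'   `"chi_square"`).
#' @export
table1_counts <- function() {
  tibble::tribble(
    ~classification, ~level, ~n, ~n_mutant, ~test,
    "inss_stage", "Non-stage 4", 312L, 5L, "chi_square",
    "inss_stage", "Stage 4", 162L, 14L, "chi_square",
    "risk_group", "Low/intermediate", 375L, 5L, "fisher",
    "risk_group", "High", 96L, 14L, "fisher",
    "sex", "Female", 253L, 12L, "chi_square",
    "sex", "Male", 221L, 7L, "chi_square",
    "mycn_fish", "Not amplified", 431L, 18L, "fisher",
    "mycn_fish", "Amplified", 39L, 1L, "fisher",
    "mycn_ngs", "Not amplified", 447L, 19L, "fisher",
    "mycn_ngs", "Amplified", 28L, 0L, "fisher",
    "alk", "No mutation", 454L, 17L, "fisher",
    "alk", "Mutation", 21L, 2L, "fisher",
    "ploidy", "Hyperdiploid", 277L, 10L, "chi_square",
    "ploidy", "Diploid", 179L, 8L, "chi_square",
    "loh_11q", "No", 301L, 5L, "fisher",
    "loh_11q", "Yes", 27L, 5L, "fisher",
    "loh_1p", "No", 290L, 9L, "fisher",
    "loh_1p", "Yes", 38L, 1L, "fisher",
    "histology", "Favorable", 314L, 1L, "fisher",
    "histology", "Unfavorable", 136L, 17L, "fisher",
    "age_18mo", "<18 months", 213L, 0L, "fisher",
    "age_18mo", ">=18 months", 261L, 19L, "fisher",
    "grade", "Differentiating", 43L, 3L, "fisher",
    "grade", "Poorly/undifferentiated", 283L, 15L, "fisher",
    "mki", "Low/intermediate", 298L, 18L, "fisher",
    "mki", "High", 32L, 0L, "fisher",
    "race", "Black", 55L, 5L, "chi_square",
    "race", "Other", 378L, 12L, "chi_square"
  )
}

#' Simulated per-patient cohort for one clinical classification
#'
#' Expands the packaged per-classification counts into a per-patient table
#' via [simulate_cohort()]; marginal counts match [table1_counts()] exactly.
#'
#' @param classification one of the values in
#'   `table1_counts()$classification`.
#' @param seed integer seed (affects only patient identity, not margins).
#' @return A tibble: `patient_id`, `stratum` (classification level),
#'   `mutant`.
#' @export
table1_cohort <- function(classification, seed = 1) {
  tc <- table1_counts()
  tc <- tc[tc$classification == classification, ]
  if (!nrow(tc)) stop("unknown classification: ", classification)
  simulate_cohort(cohort_spec(
    tibble::tibble(stratum = tc$level, n_total = tc$n, n_mutant = tc$n_mutant),
    seed = seed))
}

#' ALT status by ATRX genotype in the assayed tumors
#'
#' 2x2 counts of alternative-lengthening-of-telomeres (ALT) positivity in
#' ATRX-mutant versus ATRX-wild-type tumors: 17/19 mutant tumors were
#' ALT-positive versus 4/18 wild-type tumors.
#'
#' @return A 2x2 integer matrix (rows: ATRX mutant / wild type; columns:
#'   ALT / no ALT).
#' @export
alt_atrx_counts <- function() {
  matrix(c(17L, 2L, 4L, 14L), nrow = 2, byrow = TRUE,
         dimnames = list(c("ATRX mutant", "ATRX wild type"),
                         c("ALT", "no ALT")))
}

#' Specification of a simulated 96-well screening plate set
#'
#' Each compound occupies one row across columns 1--10 with a 1:3 dilution
#' series starting from `stock_molar / dilution_factor`; column 11 holds
#' vehicle (DMSO) wells and column 12 the positive-control wells.  The
#' cytotoxic response of each compound follows a four-parameter logistic
#' (4PL) curve on the log2-RLU scale, optionally plus a Gaussian
#' "protective bump" in log10-concentration.
#'
#' @param compounds a data frame with one row per compound (at most 8) and
#'   columns `compound`, `top`, `bottom` (log2-RLU offsets at the low- and
#'   high-concentration asymptotes), `ec50` (molar), `hill`, and optional
#'   `bump_center` (log10 molar), `bump_width`, `bump_height` (log2 RLU).
#' @param stock_molar compound stock concentration (molar).
#' @param dilution_factor fold dilution from stock into the first column.
#' @param ratio serial dilution ratio between neighboring columns.
#' @param baseline_log2 mean log2 RLU of an untreated (vehicle) well.
#' @param positive_effect log2-RLU offset of the positive-control wells.
#' @param noise_sd Gaussian noise SD on the log2-RLU scale.
#' @param n_plates replicate plates (>= 2).
#' @param seed integer seed.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(compounds,
                       stock_molar = 10e-3,
                       dilution_factor = 890,
                       ratio = 3,
                       baseline_log2 = 14,
                       positive_effect = -6,
                       noise_sd = 0.15,
                       n_plates = 2,
                       seed = 1) {
  compounds <- tibble::as_tibble(compounds)
  stopifnot(all(c("compound", "top", "bottom", "ec50", "hill") %in%
                names(compounds)),
            nrow(compounds) <= 8, nrow(compounds) >= 1,
            n_plates >= 2)
  for (cn in c("bump_center", "bump_width", "bump_height"))
    if (!cn %in% names(compounds)) compounds[[cn]] <- NA_real_
  structure(list(compounds = compounds, stock_molar = stock_molar,
                 dilution_factor = dilution_factor, ratio = ratio,
                 baseline_log2 = baseline_log2,
                 positive_effect = positive_effect,
                 noise_sd = noise_sd, n_plates = n_plates, seed = seed),
            class = "plate_spec")
}

# Expected log2-RLU offset of a compound at molar concentration conc.
.plate_curve <- function(cmp, conc) {
  x <- log10(conc)
  logistic <- cmp$bottom + (cmp$top - cmp$bottom) /
    (1 + 10^(cmp$hill * (x - log10(cmp$ec50))))
  bump <- 0
  if (!is.na(cmp$bump_center) && !is.na(cmp$bump_height) &&
      !is.na(cmp$bump_width) && cmp$bump_height != 0)
    bump <- cmp$bump_height *
      exp(-((x - cmp$bump_center)^2) / (2 * cmp$bump_width^2))
  logistic + bump
}

#' Simulate replicate screening plates
#'
#' RLU of a drugged well is
#' `2^(baseline + curve(concentration) + noise)`; vehicle wells are
#' `2^(baseline + noise)` and positive-control wells
#' `2^(baseline + positive_effect + noise)`.  Deterministic given the seed.
#'
#' @param spec a [plate_spec()].
#' @return A list with `rlu` (list of 8x12 matrices, one per plate),
#'   `layout` (tibble: `row`, `col`, `compound`, `concentration`, `role`)
#'   and the `spec`.
#' @export
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  conc <- make_dilution_series(spec$stock_molar, spec$dilution_factor,
                               steps = 10, ratio = spec$ratio)
  n_cmp <- nrow(spec$compounds)
  layout <- do.call(rbind, lapply(seq_len(8), function(r) {
    cmp <- if (r <= n_cmp) spec$compounds$compound[r] else NA_character_
    tibble::tibble(
      row = r, col = 1:12,
      compound = c(rep(cmp, 10), NA, NA),
      concentration = c(if (r <= n_cmp) conc else rep(NA_real_, 10), NA, NA),
      role = c(rep(if (r <= n_cmp) "drug" else "empty", 10),
               "vehicle", "positive_control")
    )
  }))
  with_seed(spec$seed, {
    rlu <- lapply(seq_len(spec$n_plates), function(p) {
      m <- matrix(NA_real_, 8, 12)
      for (r in seq_len(8)) {
        for (cc in seq_len(12)) {
          role <- layout$role[(r - 1) * 12 + cc]
          if (role == "empty") next
          mu <- spec$baseline_log2
          if (role == "drug")
            mu <- mu + .plate_curve(spec$compounds[r, ], conc[cc])
          else if (role == "positive_control")
            mu <- mu + spec$positive_effect
          m[r, cc] <- 2^(mu + stats::rnorm(1, 0, spec$noise_sd))
        }
      }
      m
    })
    list(rlu = rlu, layout = layout, spec = spec)
  })
}
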