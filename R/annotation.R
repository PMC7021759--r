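#' Annotate reference peaks with G4 and RLFS overlap
#'
#' Flags each peak that shares at least one base pair with a G-quadruplex
#' motif interval, and among the G4-flagged peaks those that also overlap
#' an R-loop-forming-sequence interval.  The RLFS fraction is reported
#' conditionally among G4-flagged peaks, matching the usual reporting
#' convention for these two tracks.
#'
#' @param peaks reference peak `GRanges`.
#' @param g4,rlfs `GRanges` tracks.
#' @return A list: `peaks` (with logical metadata columns `g4`, `rlfs`) and
#'   `summary` (`n_peaks`, `n_g4`, `frac_g4`, `n_g4_rlfs`,
#'   `frac_rlfs_of_g4`, `g4_empty` flag set when the conditional fraction
#'   is undefined because no peak is G4-flagged).
#' @export
annotate_g4_rloop <- function(peaks, g4, rlfs) {
  hit_g4 <- overlap_query(peaks, g4)$hit
  hit_rlfs <- overlap_query(peaks, rlfs)$hit & hit_g4
  S4Vectors::mcols(peaks)$g4 <- hit_g4
  S4Vectors::mcols(peaks)$rlfs <- hit_rlfs
  n <- length(peaks); n_g4 <- sum(hit_g4); n_g4_rlfs <- sum(hit_rlfs)
  list(
    peaks = peaks,
    summary = list(
      n_peaks = n,
      n_g4 = n_g4,
      frac_g4 = if (n > 0) n_g4 / n else 0,
      n_g4_rlfs = n_g4_rlfs,
      frac_rlfs_of_g4 = if (n_g4 > 0) n_g4_rlfs / n_g4 else 0,
      g4_empty = n_g4 == 0
    )
  )
}

#' Dominant segmentation state over an interval
#'
#' The state covering the most base pairs of the interval; ties are broken
#' toward the lowest state number; uncovered base pairs are ignored.
#'
#' @param segmentation `GRanges` with integer metadata column `state`.
#' @param interval a length-1 `GRanges`.
#' @return Integer state, or `NA_integer_` when the interval lies entirely
#'   outside the segmented territory (an "unsegmented" result).
#' @export
dominant_state <- function(segmentation, interval) {
  stopifnot(length(interval) == 1)
  cov <- .coverage_by(interval, segmentation,
                      S4Vectors::mcols(segmentation)$state)
  if (!length(cov)) return(NA_integer_)
  states <- as.integer(names(cov))
  best <- max(cov)
  min(states[cov == best])
}

#' ChromHMM-state concordance of a reference peak with its presence pattern
#'
#' Tests whether the segmentation states at the peak separate the samples
#' in which the peak is present from those in which it is absent.
#' \describe{
#'   \item{disjoint (default)}{concordant iff the sets of dominant states of
#'     peak-present and peak-absent samples are disjoint.}
#'   \item{active_class}{concordant iff every present sample's dominant
#'     state is of class active/enhancer and every absent sample's is of
#'     class inactive.}
#' }
#'
#' @param peak a length-1 `GRanges` with `present_*` metadata columns.
#' @param segmentations named list of per-sample segmentation `GRanges`.
#' @param sample_groups named character vector mapping sample id to group.
#' @param rule `"disjoint"` or `"active_class"`.
#' @param state_classes named class per state, see
#'   [default_state_classes()].
#' @return A list: `concordant` (logical, `NA` when excluded) and `reason`
#'   (`NA` or why the peak was excluded).
#' @export
state_concordance <- function(peak, segmentations, sample_groups,
                              rule = c("disjoint", "active_class"),
                              state_classes = default_state_classes()) {
  rule <- match.arg(rule)
  stopifnot(length(peak) == 1)
  mc <- S4Vectors::mcols(peak)
  present_groups <- c("ATRX", "MYCN", "WT")[c(mc$present_ATRX,
                                              mc$present_MYCN,
                                              mc$present_WT)]
  dom <- vapply(names(segmentations), function(id)
    dominant_state(segmentations[[id]], peak), integer(1))
  if (anyNA(dom))
    return(list(concordant = NA,
                reason = paste("unsegmented in sample(s):",
                               paste(names(dom)[is.na(dom)], collapse = ", "))))
  in_present <- sample_groups[names(segmentations)] %in% present_groups
  s_present <- dom[in_present]; s_absent <- dom[!in_present]
  if (!length(s_present) || !length(s_absent))
    return(list(concordant = FALSE, reason = NA_character_))
  conc <- if (rule == "disjoint") {
    length(intersect(unique(s_present), unique(s_absent))) == 0
  } else {
    all(state_classes[as.character(s_present)] %in% c("active", "enhancer")) &&
      all(state_classes[as.character(s_absent)] == "inactive")
  }
  list(concordant = conc, reason = NA_character_)
}

#' Concordance flags for a whole reference set
#'
#' @inheritParams state_concordance
#' @param peaks reference peak `GRanges`.
#' @return `peaks` with logical metadata column `chromhmm_concordant`
#'   (`NA` where excluded).
#' @export
annotate_concordance <- function(peaks, segmentations, sample_groups,
                                 rule = "disjoint",
                                 state_classes = default_state_classes()) {
  conc <- vapply(seq_along(peaks), function(i)
    state_concordance(peaks[i], segmentations, sample_groups, rule,
                      state_classes)$concordant, logical(1))
  S4Vectors::mcols(peaks)$chromhmm_concordant <- conc
  peaks
}

.promoter_windows <- function(tss_table, flank) {
  interval_set(tss_table$seq,
               pmax(0, tss_table$tss - flank),
               tss_table$tss + flank)
}

#' Promoter / enhancer / other location class of reference peaks
#'
#' A peak is a `promoter` iff it overlaps the strand-agnostic window
#' `[TSS - 2 kb, TSS + 2 kb)` of any gene; otherwise it is an `enhancer`
#' iff its dominant state in any peak-present sample is of class enhancer;
#' otherwise `other`.
#'
#' @param peaks reference peak `GRanges` with `present_*` columns.
#' @param tss_table tibble with columns `seq`, `tss` (0-based bp).
#' @param segmentations named list of per-sample segmentation `GRanges`.
#' @param sample_groups named character vector mapping sample id to group.
#' @param flank promoter half-window (bp).
#' @param state_classes named class per state.
#' @return `peaks` with metadata column `location` (factor: promoter,
#'   enhancer, other).
#' @export
location_class <- function(peaks, tss_table, segmentations, sample_groups,
                           flank = 2000,
                           state_classes = default_state_classes()) {
  prom <- overlap_query(peaks, .promoter_windows(tss_table, flank))$hit
  loc <- rep("other", length(peaks))
  loc[prom] <- "promoter"
  mc <- S4Vectors::mcols(peaks)
  for (i in which(!prom)) {
    present_groups <- c("ATRX", "MYCN", "WT")[c(mc$present_ATRX[i],
                                                mc$present_MYCN[i],
                                                mc$present_WT[i])]
    ids <- names(segmentations)[sample_groups[names(segmentations)] %in%
                                present_groups]
    dom <- vapply(ids, function(id)
      dominant_state(segmentations[[id]], peaks[i]), integer(1))
    dom <- dom[!is.na(dom)]
    if (length(dom) && any(state_classes[as.character(dom)] == "enhancer"))
      loc[i] <- "enhancer"
  }
  S4Vectors::mcols(peaks)$location <-
    factor(loc, levels = c("promoter", "enhancer", "other"))
  peaks
}

#' State-13 expansion downstream of gene promoters
#'
#' For every gene, computes the fraction of the strand-aware downstream
#' window (`[TSS, TSS + 2 kb)` on `+`, `[TSS - 2 kb, TSS)` on `-`) covered
#' by state 13 (strongly transcribed gene body) in two conditions, and
#' flags the gene as expanded iff the condition-plus proportion is more
#' than twice the condition-minus proportion and at least 20%.
#'
#' @param segmentation_plus,segmentation_minus per-condition segmentation
#'   `GRanges` (e.g. MYCN-induced vs uninduced).
#' @param tss_table tibble with `gene_id`, `seq`, `tss`, `strand`.
#' @param window downstream window size (bp).
#' @param state the gene-body state number.
#' @param min_prop minimum condition-plus proportion.
#' @param fold required fold increase.
#' @return A tibble: `gene_id`, `prop_plus`, `prop_minus`, `expanded`.
#' @export
state13_expansion <- function(segmentation_plus, segmentation_minus,
                              tss_table, window = 2000, state = 13L,
                              min_prop = 0.20, fold = 2) {
  if (any(!tss_table$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-' (downstream is undefined otherwise)")
  dn_start <- ifelse(tss_table$strand == "+", tss_table$tss,
                     pmax(0, tss_table$tss - window))
  dn_end <- ifelse(tss_table$strand == "+", tss_table$tss + window,
                   tss_table$tss)
  win <- interval_set(tss_table$seq, dn_start, dn_end)
  prop_in <- function(seg) {
    vapply(seq_along(win), function(i) {
      cov <- .coverage_by(win[i], seg, S4Vectors::mcols(seg)$state)
      tot <- interval_width(win[i])
      s <- cov[as.character(state)]
      if (is.na(s) || is.null(s)) 0 else unname(s) / tot
    }, numeric(1))
  }
  prop_plus <- prop_in(segmentation_plus)
  prop_minus <- prop_in(segmentation_minus)
  tibble::tibble(
    gene_id = tss_table$gene_id,
    prop_plus = prop_plus,
    prop_minus = prop_minus,
    expanded = prop_plus > fold * prop_minus & prop_plus >= min_prop
  )
}

#' MYCN promoter-binding call per gene
#'
#' A gene has a MYCN-binding site iff any MYCN peak overlaps its promoter
#' window `[TSS - 2 kb, TSS + 2 kb)` (strand-agnostic).
#'
#' @param tss_table tibble with `gene_id`, `seq`, `tss`.
#' @param mycn_peaks `GRanges` of MYCN peak calls.
#' @param flank promoter half-window (bp).
#' @return A tibble: `gene_id`, `mycn_bound` (logical).
#' @export
mycn_promoter_binding <- function(tss_table, mycn_peaks, flank = 2000) {
  win <- .promoter_windows(tss_table, flank)
  tibble::tibble(gene_id = tss_table$gene_id,
                 mycn_bound = overlap_query(win, mycn_peaks)$hit)
}

#' Associate filtered DMRs with promoters of differentially expressed genes
#'
#' Differentially methylated regions are first filtered on the validity
#' rules (length >= 50 bp, >= 3 CpG sites, |methylation difference| >= 0.2,
#' caller p <= 0.01); surviving DMRs are paired with genes whose promoter
#' window `[TSS - 1 kb, TSS + 1 kb)` they overlap and whose expression
#' change passes |log2 fold| >= 1 at adjusted p <= 0.1.
#'
#' @param dmrs tibble with `seq`, `start`, `end`, `n_cpg`, `meth_diff`, `p`.
#' @param tss_table tibble with `gene_id`, `seq`, `tss`.
#' @param deg_table tibble with `gene_id`, `log2_fold`, `adj_p`.
#' @param flank promoter half-window (bp).
#' @param min_length,min_cpg,min_meth_diff,max_p DMR validity thresholds.
#' @param min_abs_log2_fold,max_deg_adj_p DEG thresholds.
#' @return A tibble of associated pairs: DMR coordinates plus `gene_id`.
#' @export
dmr_promoter_deg_intersect <- function(dmrs, tss_table, deg_table,
                                       flank = 1000,
                                       min_length = 50, min_cpg = 3,
                                       min_meth_diff = 0.2, max_p = 0.01,
                                       min_abs_log2_fold = 1,
                                       max_deg_adj_p = 0.1) {
  dmrs <- tibble::as_tibble(dmrs)
  keep <- (dmrs$end - dmrs$start) >= min_length &
    dmrs$n_cpg >= min_cpg &
    abs(dmrs$meth_diff) >= min_meth_diff &
    dmrs$p <= max_p
  dmrs <- dmrs[keep, , drop = FALSE]
  empty <- tibble::tibble(seq = character(0), start = numeric(0),
                          end = numeric(0), n_cpg = numeric(0),
                          meth_diff = numeric(0), p = numeric(0),
                          gene_id = character(0))
  if (!nrow(dmrs)) return(empty)
  deg <- deg_table[abs(deg_table$log2_fold) >= min_abs_log2_fold &
                   deg_table$adj_p <= max_deg_adj_p, , drop = FALSE]
  genes <- tss_table[tss_table$gene_id %in% deg$gene_id, , drop = FALSE]
  if (!nrow(genes)) return(empty)
  dmr_gr <- interval_set(dmrs$seq, dmrs$start, dmrs$end)
  win <- .promoter_windows(genes, flank)
  al <- .align_seqlevels(dmr_gr, win)
  ov <- GenomicRanges::findOverlaps(al$x, al$y, minoverlap = 1L,
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- dmrs[qi, c("seq", "start", "end", "n_cpg", "meth_diff", "p")]
  out$gene_id <- genes$gene_id[si]
  tibble::as_tibble(out)
}
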