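#' QC gating of ChIP/CUT&RUN sample tracks
#'
#' Applies the read-depth and relative-strand-correlation (RSC) rules used
#' to admit samples into the chromatin analysis:
#' \itemize{
#'   \item point-source factors pass with >= 10 million unique reads and
#'     RSC > 1;
#'   \item broad marks pass with >= 20 million unique reads (RSC is
#'     recorded but not gated);
#'   \item input controls pass with >= 10 million unique reads and RSC < 1.
#' }
#'
#' @param qc a data frame with columns `sample`, `mark_class`
#'   (`"point_source"`, `"broad"` or `"input"`), `unique_reads`, `rsc`.
#' @return The input tibble with added `pass` (logical) and `reason`
#'   (`NA` for passing samples; otherwise the violated rule).
#' @export
qc_filter <- function(qc) {
  qc <- tibble::as_tibble(qc)
  stopifnot(all(c("sample", "mark_class", "unique_reads", "rsc") %in% names(qc)))
  bad <- setdiff(unique(qc$mark_class), c("point_source", "broad", "input"))
  if (length(bad))
    stop("unknown mark_class: ", paste(bad, collapse = ", "))
  reason <- rep(NA_character_, nrow(qc))
  for (i in seq_len(nrow(qc))) {
    mc <- qc$mark_class[i]; ur <- qc$unique_reads[i]; rsc <- qc$rsc[i]
    reason[i] <- if (mc == "point_source") {
      if (ur < 10e6) "unique_reads < 10e6 (point source)"
      else if (rsc <= 1) "rsc <= 1 (point source)"
      else NA_character_
    } else if (mc == "broad") {
      if (ur < 20e6) "unique_reads < 20e6 (broad mark)" else NA_character_
    } else {
      if (ur < 10e6) "unique_reads < 10e6 (input)"
      else if (rsc >= 1) "rsc >= 1 (input)"
      else NA_character_
    }
  }
  qc$pass <- is.na(reason)
  qc$reason <- reason
  qc
}

#' Compile the reproducible peak set of one genotype group
#'
#' A sample's high-confidence peak (caller FDR 0.05) is retained iff it
#' overlaps at least one low-confidence peak (caller FDR 0.5) of another
#' sample in the same group (`support = "any"`), or of every other sample
#' (`support = "all"`).  With two replicates per group the two readings
#' coincide.  The retained peaks of all samples are merged.
#'
#' @param samples a list of sample tracks; each element a list with
#'   elements `high` and `low` (`GRanges`).
#' @param support `"any"` (default) or `"all"`.
#' @return A merged `GRanges` of reproducible peaks.
#' @export
compile_reproducible_peaks <- function(samples, support = c("any", "all")) {
  support <- match.arg(support)
  if (length(samples) < 2)
    stop("reproducibility requires >= 2 samples per group")
  retained <- list()
  for (i in seq_along(samples)) {
    high <- samples[[i]]$high
    if (!length(high)) next
    others <- samples[-i]
    sup <- vapply(others, function(o) overlap_query(high, o$low)$hit,
                  logical(length(high)))
    if (length(high) == 1) sup <- matrix(sup, nrow = 1)
    keep <- if (support == "any") rowSums(sup) >= 1
            else rowSums(sup) == length(others)
    retained[[i]] <- high[keep]
  }
  retained <- retained[!vapply(retained, is.null, logical(1))]
  if (!length(retained))
    return(GenomicRanges::GRanges())
  merge_intervals(do.call(c, unname(retained)))
}

#' Build the reference peak set across the three genotype groups
#'
#' Merges the union of the per-group reproducible peak sets; each merged
#' reference interval is flagged as present in a group iff it overlaps that
#' group's reproducible set.
#'
#' @param group_sets named list of `GRanges`, names `ATRX`, `MYCN`, `WT`.
#' @return A `GRanges` with logical metadata columns `present_ATRX`,
#'   `present_MYCN`, `present_WT`.
#' @export
build_reference_peaks <- function(group_sets) {
  stopifnot(all(c("ATRX", "MYCN", "WT") %in% names(group_sets)))
  ref <- merge_intervals(do.call(c, unname(group_sets[c("ATRX", "MYCN", "WT")])))
  for (g in c("ATRX", "MYCN", "WT"))
    S4Vectors::mcols(ref)[[paste0("present_", g)]] <-
      overlap_query(ref, group_sets[[g]])$hit
  ref
}

#' Count size-filtered fragments over the reference peaks
#'
#' A fragment contributes iff its length is strictly below
#' `max_fragment_size`; it increments every reference peak it overlaps by at
#' least one base pair (no double-count correction).  The per-sample library
#' size is the number of size-passing fragments.
#'
#' @param tracks list of sample tracks; each a list with `id` and
#'   `fragments` (`GRanges`).
#' @param reference reference peak `GRanges`.
#' @param max_fragment_size exclusive fragment-size cutoff (bp).
#' @return An integer matrix (peaks x samples) with attribute
#'   `library_sizes` (named integer vector).
#' @export
count_fragments <- function(tracks, reference, max_fragment_size = 2000) {
  ids <- vapply(tracks, `[[`, character(1), "id")
  counts <- matrix(0L, nrow = length(reference), ncol = length(tracks),
                   dimnames = list(NULL, ids))
  libsize <- integer(length(tracks)); names(libsize) <- ids
  for (j in seq_along(tracks)) {
    fr <- tracks[[j]]$fragments
    if (!length(fr)) {
      warning("sample ", ids[j], " has no fragments; zero column")
      next
    }
    fr <- fr[interval_width(fr) < max_fragment_size]
    libsize[j] <- length(fr)
    counts[, j] <- overlap_count(reference, fr)
  }
  attr(counts, "library_sizes") <- libsize
  counts
}

# Invert trigamma by Newton iteration (monotone decreasing on (0, Inf)).
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Empirical-Bayes variance moderation: method of moments on log s^2
# (Smyth-style).  Returns prior df d0, prior variance s2_0 and posterior
# variances.
.squeeze_var <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (!any(ok))
    return(list(d0 = Inf, s2_0 = 0, s2_post = rep(0, length(s2))))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  ev <- if (sum(ok) > 1) stats::var(e) * (sum(ok) - 1) / sum(ok) else 0
  resid_var <- ev - trigamma(df / 2)
  if (resid_var <= 0) {
    d0 <- Inf
    s2_0 <- exp(ebar)
    s2_post <- rep(s2_0, length(s2))
  } else {
    d0 <- 2 * .trigamma_inverse(resid_var)
    s2_0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s2_0 + df * s2) / (d0 + df)
    s2_post[!ok] <- (d0 * s2_0) / (d0 + df)
  }
  list(d0 = d0, s2_0 = s2_0, s2_post = s2_post)
}

#' Moderated differential-occupancy test between genotype groups
#'
#' Fragment counts are converted to log2 counts-per-million with a
#' pseudocount of 0.5; for each of the two contrasts (ATRX vs MYCN, ATRX vs
#' WT) a per-peak two-sample t statistic is computed with the pooled
#' variance shrunk toward a common prior by empirical Bayes (method of
#' moments on the log residual variances), and p-values are
#' Benjamini-Hochberg adjusted within each contrast.  Positive log
#' fold-changes mean higher occupancy in the ATRX group.
#'
#' @param counts matrix from [count_fragments()] (peaks x samples) with a
#'   `library_sizes` attribute, or any non-negative count matrix (library
#'   sizes default to column sums).
#' @param groups character vector, one of `ATRX`/`MYCN`/`WT` per column.
#' @return A tibble with one row per peak: `logFC_mycn`, `t_mycn`,
#'   `p_mycn`, `adj_p_mycn` and the same for `_wt`.
#' @export
differential_occupancy <- function(counts, groups) {
  stopifnot(ncol(counts) == length(groups))
  libsize <- attr(counts, "library_sizes")
  if (is.null(libsize)) libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  for (g in c("ATRX", "MYCN", "WT"))
    if (sum(groups == g) < 2)
      stop("need >= 2 samples in group ", g)
  logcpm <- log2(t((t(counts) + 0.5) / (libsize + 1) * 1e6))
  res_m <- .moderated_contrast(logcpm, groups == "ATRX", groups == "MYCN")
  res_w <- .moderated_contrast(logcpm, groups == "ATRX", groups == "WT")
  tibble::tibble(
    logFC_mycn = res_m$logFC, t_mycn = res_m$t, p_mycn = res_m$p,
    adj_p_mycn = stats::p.adjust(res_m$p, "BH"),
    logFC_wt = res_w$logFC, t_wt = res_w$t, p_wt = res_w$p,
    adj_p_wt = stats::p.adjust(res_w$p, "BH")
  )
}

.moderated_contrast <- function(logcpm, idx1, idx2) {
  x1 <- logcpm[, idx1, drop = FALSE]
  x2 <- logcpm[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  sq <- .squeeze_var(s2, df)
  logFC <- m1 - m2
  se <- sqrt(sq$s2_post * (1 / n1 + 1 / n2))
  t <- logFC / se
  df_total <- if (is.finite(sq$d0)) df + sq$d0 else Inf
  p <- 2 * stats::pt(-abs(t), df = df_total)
  # degenerate rows: no variability anywhere and no difference
  zero <- se == 0
  t[zero & logFC == 0] <- 0
  p[zero & logFC == 0] <- 1
  t[zero & logFC != 0] <- sign(logFC[zero & logFC != 0]) * Inf
  p[zero & logFC != 0] <- 0
  list(logFC = logFC, t = t, p = p)
}

#' Classify reference peaks into C/E/D/O occupancy groups
#'
#' Presence mode uses the per-group presence pattern only: `C` when present
#' in all three groups, `E` when present only in ATRX, `D` when absent in
#' ATRX but present in MYCN and WT, `O` when present in ATRX plus exactly
#' one of MYCN/WT, and `unclassified` otherwise.  The `presence+stats` mode
#' additionally requires, for `E` (respectively `D`), adjusted p <= `alpha`
#' and a log fold-change with ATRX higher (respectively lower) in both
#' contrasts.
#'
#' @param reference `GRanges` from [build_reference_peaks()].
#' @param stats tibble from [differential_occupancy()] (required for
#'   `presence+stats`).
#' @param mode `"presence"` (default) or `"presence+stats"`.
#' @param alpha adjusted-p threshold for the stats-gated mode.
#' @return `reference` with an added metadata column `label` (factor with
#'   levels `C`, `E`, `D`, `O`, `unclassified`).
#' @export
classify_peak_groups <- function(reference, stats = NULL,
                                 mode = c("presence", "presence+stats"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  mc <- S4Vectors::mcols(reference)
  a <- mc$present_ATRX; m <- mc$present_MYCN; w <- mc$present_WT
  label <- rep("unclassified", length(reference))
  label[a & m & w] <- "C"
  label[a & !m & !w] <- "E"
  label[!a & m & w] <- "D"
  label[a & xor(m, w)] <- "O"
  if (mode == "presence+stats") {
    if (is.null(stats))
      stop("mode 'presence+stats' requires differential statistics")
    sig_up <- stats$adj_p_mycn <= alpha & stats$adj_p_wt <= alpha &
      stats$logFC_mycn > 0 & stats$logFC_wt > 0
    sig_dn <- stats$adj_p_mycn <= alpha & stats$adj_p_wt <= alpha &
      stats$logFC_mycn < 0 & stats$logFC_wt < 0
    label[label == "E" & !sig_up] <- "unclassified"
    label[label == "D" & !sig_dn] <- "unclassified"
  }
  S4Vectors::mcols(reference)$label <-
    factor(label, levels = c("C", "E", "D", "O", "unclassified"))
  reference
}

#' Run the full peak-landscape pipeline on a simulated bundle
#'
#' Convenience wrapper: compiles per-group reproducible peaks, builds the
#' reference set, counts size-filtered fragments, runs the moderated
#' differential test and classifies peaks.
#'
#' @param bundle a [simulate_peak_landscape()] bundle.
#' @param mode classification mode, see [classify_peak_groups()].
#' @param support reproducibility support rule, see
#'   [compile_reproducible_peaks()].
#' @param max_fragment_size fragment-size cutoff for counting.
#' @return A list with `reference` (labelled `GRanges`), `counts`, `stats`
#'   and the per-group reproducible `group_sets`.
#' @export
classify_landscape <- function(bundle, mode = "presence", support = "any",
                               max_fragment_size = 2000) {
  groups <- vapply(bundle$samples, `[[`, character(1), "group")
  group_sets <- lapply(c(ATRX = "ATRX", MYCN = "MYCN", WT = "WT"), function(g)
    compile_reproducible_peaks(bundle$samples[groups == g], support = support))
  reference <- build_reference_peaks(group_sets)
  counts <- count_fragments(bundle$samples, reference,
                            max_fragment_size = max_fragment_size)
  stats <- differential_occupancy(counts, groups)
  reference <- classify_peak_groups(reference, stats, mode = mode)
  list(reference = reference, counts = counts, stats = stats,
       group_sets = group_sets)
}
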