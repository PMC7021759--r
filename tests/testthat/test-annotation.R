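test_that("G4/RLFS annotation handles empty and identity tracks", {
  peaks <- interval_set("a", c(0, 100, 200), c(50, 150, 250))
  empty <- GenomicRanges::GRanges()
  res <- annotate_g4_rloop(peaks, empty, empty)
  expect_equal(res$summary$frac_g4, 0)
  expect_equal(res$summary$frac_rlfs_of_g4, 0)
  expect_true(res$summary$g4_empty)

  res <- annotate_g4_rloop(peaks, peaks, empty)
  expect_equal(res$summary$frac_g4, 1)
  expect_equal(res$summary$n_g4_rlfs, 0)
})

test_that("G4/RLFS totals are nested: n_g4_rlfs <= n_g4 <= n_peaks", {
  set.seed(7)
  for (rep in 1:5) {
    peaks <- df_to_gr(random_intervals_df(100))
    g4 <- df_to_gr(random_intervals_df(60))
    rlfs <- df_to_gr(random_intervals_df(60))
    s <- annotate_g4_rloop(peaks, g4, rlfs)$summary
    expect_lte(s$n_g4_rlfs, s$n_g4)
    expect_lte(s$n_g4, s$n_peaks)
  }
})

test_that("planted G4 fraction is recovered by annotation", {
  tr <- landscape_truth(n_per_label = c(C = 50, E = 50, D = 50, O = 50),
                        g4_fraction = 0.35, min_gap = 500, seed = 19)
  b <- simulate_peak_landscape(tr, jitter = 0, noise_rate = 0,
                               low_only_rate = 0)
  ref <- classify_landscape(b)$reference
  s <- annotate_g4_rloop(ref, b$g4, b$rlfs)$summary
  expect_equal(s$frac_g4, mean(tr$planted_peaks$g4))
  expect_equal(s$frac_rlfs_of_g4,
               mean(tr$planted_peaks$rlfs[tr$planted_peaks$g4]))
})

test_that("dominant state takes the majority with low-state tie-break", {
  seg <- interval_set("a", c(0, 60), c(60, 100), state = c(2L, 16L))
  expect_equal(dominant_state(seg, interval_set("a", 0, 100)), 2L)
  expect_equal(dominant_state(seg, interval_set("a", 70, 90)), 16L)
  # exact 50/50 split: lowest state wins
  seg <- interval_set("a", c(0, 50), c(50, 100), state = c(15L, 4L))
  expect_equal(dominant_state(seg, interval_set("a", 0, 100)), 4L)
  # single cover
  seg13 <- interval_set("a", 0, 1000, state = 13L)
  expect_equal(dominant_state(seg13, interval_set("a", 10, 20)), 13L)
  # fully unsegmented interval
  expect_true(is.na(dominant_state(seg13, interval_set("b", 0, 10))))
  # invariant to splitting a segment into abutting same-state pieces
  seg_split <- interval_set("a", c(0, 400), c(400, 1000), state = c(13L, 13L))
  expect_equal(dominant_state(seg_split, interval_set("a", 10, 900)), 13L)
})

test_that("state concordance separates present from absent samples", {
  peak <- interval_set("a", 100, 200)
  S4Vectors::mcols(peak)$present_ATRX <- FALSE
  S4Vectors::mcols(peak)$present_MYCN <- TRUE
  S4Vectors::mcols(peak)$present_WT <- TRUE
  mkseg <- function(state) interval_set("a", 0, 1000, state = state)
  segs <- list(A1 = mkseg(16L), M1 = mkseg(3L), W1 = mkseg(3L))
  grp <- c(A1 = "ATRX", M1 = "MYCN", W1 = "WT")
  expect_true(state_concordance(peak, segs, grp, "disjoint")$concordant)
  expect_true(state_concordance(peak, segs, grp, "active_class")$concordant)
  # no shift: all samples state 13
  segs13 <- list(A1 = mkseg(13L), M1 = mkseg(13L), W1 = mkseg(13L))
  expect_false(state_concordance(peak, segs13, grp, "disjoint")$concordant)
  # unsegmented in one sample -> excluded with reason
  segs_na <- segs; segs_na$A1 <- interval_set("b", 0, 10, state = 1L)
  r <- state_concordance(peak, segs_na, grp)
  expect_true(is.na(r$concordant))
  expect_match(r$reason, "unsegmented")
})

test_that("planted state shifts make all D peaks concordant at zero noise", {
  b <- make_clean_bundle(seed = 47)
  res <- classify_landscape(b)
  segs <- lapply(b$samples, `[[`, "segmentation")
  grp <- vapply(b$samples, `[[`, character(1), "group")
  ref <- annotate_concordance(res$reference, segs, grp)
  mc <- S4Vectors::mcols(ref)
  expect_true(all(mc$chromhmm_concordant[mc$label == "D"]))
})

test_that("location class applies promoter window then enhancer state", {
  tss <- tibble::tibble(gene_id = "g1", seq = "a", tss = 10000,
                        strand = "+")
  segs <- list(s1 = interval_set("a", 0, 50000, state = 6L))
  grp <- c(s1 = "ATRX")
  mkpeak <- function(st, en) {
    p <- interval_set("a", st, en)
    S4Vectors::mcols(p)$present_ATRX <- TRUE
    S4Vectors::mcols(p)$present_MYCN <- FALSE
    S4Vectors::mcols(p)$present_WT <- FALSE
    p
  }
  at_tss <- location_class(mkpeak(9900, 10100), tss, segs, grp)
  expect_equal(as.character(S4Vectors::mcols(at_tss)$location), "promoter")
  # window is [TSS-2000, TSS+2000): a peak starting exactly at TSS+2000 misses
  boundary <- location_class(mkpeak(12000, 12100), tss, segs, grp)
  expect_equal(as.character(S4Vectors::mcols(boundary)$location), "enhancer")
  # enhancer-class dominant state far from any TSS
  far <- location_class(mkpeak(40000, 40100), tss, segs, grp)
  expect_equal(as.character(S4Vectors::mcols(far)$location), "enhancer")
  # same peak with a non-enhancer state -> other
  segs9 <- list(s1 = interval_set("a", 0, 50000, state = 9L))
  far9 <- location_class(mkpeak(40000, 40100), tss, segs9, grp)
  expect_equal(as.character(S4Vectors::mcols(far9)$location), "other")
})

test_that("state-13 expansion applies the fold and floor rules", {
  tss <- tibble::tibble(gene_id = c("g1", "g2", "g3"), seq = "a",
                        tss = c(10000, 30000, 50000),
                        strand = c("+", "+", "+"))
  mkseg <- function(props) {
    # cover fraction `props[i]` of [tss_i, tss_i+2000) with state 13
    pieces <- list()
    for (i in seq_along(props)) {
      t0 <- tss$tss[i]
      if (props[i] > 0)
        pieces[[length(pieces) + 1]] <-
          interval_set("a", t0, t0 + round(2000 * props[i]), state = 13L)
    }
    covered <- if (length(pieces)) do.call(c, pieces) else
      GenomicRanges::GRanges()
    rest <- GenomicRanges::setdiff(interval_set("a", 0, 60000), covered,
                                   ignore.strand = TRUE)
    S4Vectors::mcols(rest)$state <- 9L
    GenomicRanges::sort(c(covered, rest))
  }
  plus <- mkseg(c(0.25, 0.20, 0.40))
  minus <- mkseg(c(0.10, 0.00, 0.25))
  res <- state13_expansion(plus, minus, tss)
  expect_equal(res$prop_plus, c(0.25, 0.20, 0.40))
  expect_equal(res$prop_minus, c(0.10, 0.00, 0.25))
  # 0.25 vs 0.10 expands; 0.20 vs 0 expands (floor inclusive);
  # 0.40 vs 0.25 fails the fold rule
  expect_equal(res$expanded, c(TRUE, TRUE, FALSE))
  # strand-aware window: a minus-strand gene reads upstream in coordinates
  tss_m <- tibble::tibble(gene_id = "gm", seq = "a", tss = 10000,
                          strand = "-")
  segm <- mkseg(c(0.25))  # covers [10000, 10500): downstream only for "+"
  resm <- state13_expansion(segm, segm, tss_m)
  expect_equal(resm$prop_plus, 0)
  expect_error(state13_expansion(plus, minus,
                                 tibble::tibble(gene_id = "x", seq = "a",
                                                tss = 1, strand = "*")),
               "strand")
})

test_that("MYCN promoter binding respects the half-open +/-2 kb window", {
  tss <- tibble::tibble(gene_id = c("g1", "g2"), seq = "a",
                        tss = c(10000, 50000))
  peaks <- interval_set("a", c(9900, 47900), c(10100, 48000))
  res <- mycn_promoter_binding(tss, peaks)
  # g1: peak straddles the TSS; g2: peak ends exactly at TSS-2000 -> no hit
  expect_equal(res$mycn_bound, c(TRUE, FALSE))
  # brute-force agreement on random fixtures
  set.seed(3)
  tssr <- tibble::tibble(gene_id = paste0("g", 1:50), seq = "a",
                         tss = floor(runif(50, 3000, 100000)))
  pk <- random_intervals_df(200, seqs = "a", max_pos = 100000)
  got <- mycn_promoter_binding(tssr, df_to_gr(pk))$mycn_bound
  win <- data.frame(seq = "a", start = tssr$tss - 2000,
                    end = tssr$tss + 2000)
  expect_equal(got, oracle_overlap_hit(win, pk))
})

test_that("DMR-promoter-DEG intersection applies every gate", {
  tss <- tibble::tibble(gene_id = "g1", seq = "a", tss = 10000)
  deg <- tibble::tibble(gene_id = "g1", log2_fold = log2(2.5), adj_p = 0.05)
  base <- tibble::tibble(seq = "a", start = 9950, end = 10070,
                         n_cpg = 5, meth_diff = 0.25, p = 0.005)
  expect_equal(dmr_promoter_deg_intersect(base, tss, deg)$gene_id, "g1")
  # each validity gate in turn
  short <- base; short$end <- base$start + 49
  expect_equal(nrow(dmr_promoter_deg_intersect(short, tss, deg)), 0)
  few <- base; few$n_cpg <- 2
  expect_equal(nrow(dmr_promoter_deg_intersect(few, tss, deg)), 0)
  weak <- base; weak$meth_diff <- 0.1
  expect_equal(nrow(dmr_promoter_deg_intersect(weak, tss, deg)), 0)
  insig <- base; insig$p <- 0.02
  expect_equal(nrow(dmr_promoter_deg_intersect(insig, tss, deg)), 0)
  # DEG gates
  deg_weak <- tibble::tibble(gene_id = "g1", log2_fold = 0.5, adj_p = 0.05)
  expect_equal(nrow(dmr_promoter_deg_intersect(base, tss, deg_weak)), 0)
  deg_ns <- tibble::tibble(gene_id = "g1", log2_fold = 2, adj_p = 0.2)
  expect_equal(nrow(dmr_promoter_deg_intersect(base, tss, deg_ns)), 0)
  # promoter window is +/- 1 kb, half-open
  far <- base; far$start <- 11000; far$end <- 11120
  expect_equal(nrow(dmr_promoter_deg_intersect(far, tss, deg)), 0)
})
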