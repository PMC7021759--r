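test_that("qc gating applies the depth and RSC rules per mark class", {
  qc <- tibble::tibble(
    sample = c("a", "b", "c", "d", "e"),
    mark_class = c("point_source", "point_source", "broad", "broad", "input"),
    unique_reads = c(12e6, 12e6, 19e6, 21e6, 11e6),
    rsc = c(1.3, 0.9, 1.5, 0.4, 1.2)
  )
  res <- qc_filter(qc)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_match(res$reason[2], "rsc")
  expect_match(res$reason[3], "20e6")
  expect_match(res$reason[5], "rsc")
  expect_error(qc_filter(tibble::tibble(sample = "x", mark_class = "odd",
                                        unique_reads = 1, rsc = 1)),
               "unknown mark_class")
})

test_that("reproducible peaks require cross-sample low-confidence support", {
  s1 <- list(high = interval_set("a", 100, 200),
             low = interval_set("a", 100, 200))
  s2 <- list(high = interval_set("a", c(150, 900), c(400, 950)),
             low = interval_set("a", 150, 400))
  got <- compile_reproducible_peaks(list(s1, s2))
  # s1's high is supported by s2's low; s2's first high by s1's low;
  # s2's peak at 900 has no support in the other sample
  expect_equal(interval_start(got), 100)
  expect_equal(interval_end(got), 400)

  # low-confidence support must come from the same sequence
  s1b <- list(high = interval_set("a", 100, 200),
              low = interval_set("c", 0, 50))
  s2b <- list(high = interval_set("a", 900, 950),
              low = interval_set("b", 0, 1000))
  got <- compile_reproducible_peaks(list(s1b, s2b))
  expect_equal(length(got), 0)

  expect_error(compile_reproducible_peaks(list(s1)), ">= 2 samples")
})

test_that("any/all support readings coincide with two replicates", {
  set.seed(31)
  samples <- lapply(1:2, function(i) {
    df <- random_intervals_df(60, seqs = "a", max_pos = 20000)
    list(high = df_to_gr(df), low = df_to_gr(random_intervals_df(
      80, seqs = "a", max_pos = 20000)))
  })
  a <- compile_reproducible_peaks(samples, support = "any")
  b <- compile_reproducible_peaks(samples, support = "all")
  expect_equal(gr_to_df(a), gr_to_df(b))
})

test_that("retained peaks match a brute-force all-pairs support scan", {
  set.seed(13)
  for (rep in 1:3) {
    samples <- lapply(1:3, function(i) {
      list(high = df_to_gr(random_intervals_df(80)),
           low = df_to_gr(random_intervals_df(120)))
    })
    got <- compile_reproducible_peaks(samples)
    kept <- list()
    for (i in 1:3) {
      h <- gr_to_df(samples[[i]]$high)
      support <- rep(FALSE, nrow(h))
      for (j in setdiff(1:3, i))
        support <- support | oracle_overlap_hit(h, gr_to_df(samples[[j]]$low))
      kept[[i]] <- h[support, ]
    }
    want <- oracle_merge(do.call(rbind, kept))
    got_df <- gr_to_df(got)
    rownames(want) <- rownames(got_df) <- NULL
    expect_equal(got_df, want)
  }
})

test_that("reference peaks carry per-group presence from overlap", {
  gs <- list(ATRX = interval_set("a", c(0, 500), c(100, 600)),
             MYCN = interval_set("a", c(50, 900), c(150, 1000)),
             WT = interval_set("a", 0, 100))
  ref <- build_reference_peaks(gs)
  mc <- S4Vectors::mcols(ref)
  # first merged interval spans 0-150 built from ATRX+MYCN+WT
  expect_equal(interval_start(ref), c(0, 500, 900))
  expect_equal(interval_end(ref), c(150, 600, 1000))
  expect_equal(mc$present_ATRX, c(TRUE, TRUE, FALSE))
  expect_equal(mc$present_MYCN, c(TRUE, FALSE, TRUE))
  expect_equal(mc$present_WT, c(TRUE, FALSE, FALSE))
})

test_that("fragment counting applies the strict size cutoff and multi-peak hits", {
  ref <- interval_set("a", c(0, 1000), c(500, 1500))
  tr <- list(list(id = "s1", fragments = interval_set(
    "a", c(10, 100, 400), c(2010, 300, 1200))))
  # fragment 1 has length exactly 2000 -> excluded (strict <)
  cnt <- count_fragments(tr, ref)
  expect_equal(unname(cnt[, 1]), c(2L, 1L))  # frag 3 spans both peaks
  expect_equal(unname(attr(cnt, "library_sizes")), 2L)
  # empty fragments: zero column with warning
  tr0 <- list(list(id = "s0", fragments = GenomicRanges::GRanges()))
  expect_warning(cnt0 <- count_fragments(tr0, ref), "no fragments")
  expect_equal(unname(cnt0[, 1]), c(0L, 0L))
})

test_that("fragment counts equal a brute-force per-fragment scan", {
  set.seed(23)
  ref <- merge_intervals(df_to_gr(random_intervals_df(150)))
  frag_df <- random_intervals_df(600, max_width = 2500)
  tr <- list(list(id = "s", fragments = df_to_gr(frag_df)))
  got <- count_fragments(tr, ref, max_fragment_size = 2000)
  keep <- (frag_df$end - frag_df$start) < 2000
  want <- oracle_overlap_count(gr_to_df(ref), frag_df[keep, ])
  expect_equal(unname(got[, 1]), want)
  expect_equal(unname(attr(got, "library_sizes")), sum(keep))
})

test_that("the moderated test returns the null identity on constant counts", {
  cnt <- matrix(50L, nrow = 20, ncol = 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  st <- differential_occupancy(cnt, rep(c("ATRX", "MYCN", "WT"), each = 2))
  expect_equal(st$logFC_mycn, rep(0, 20))
  expect_equal(st$p_mycn, rep(1, 20))
  expect_equal(st$p_wt, rep(1, 20))
})

test_that("planted depletion in ATRX gives negative log fold-changes", {
  set.seed(41)
  base <- rpois(100, 200) + 50
  # deplete half the peaks 4-fold in ATRX; the other half anchors the
  # library-size normalization so the depletion is visible after CPM
  dep <- rep(c(TRUE, FALSE), each = 50)
  atrx_lambda <- ifelse(dep, base / 4, base)
  cnt <- cbind(matrix(rpois(200, atrx_lambda), 100),
               matrix(rpois(200, base), 100),
               matrix(rpois(200, base), 100))
  colnames(cnt) <- paste0("s", 1:6)
  st <- differential_occupancy(cnt, rep(c("ATRX", "MYCN", "WT"), each = 2))
  expect_true(all(st$logFC_mycn[dep] < 0))
  expect_true(all(st$logFC_wt[dep] < 0))
  expect_true(all(st$logFC_mycn[!dep] > 0))
})

test_that("statistics are invariant to permuting samples within a group", {
  set.seed(43)
  cnt <- matrix(rpois(600, 100), 100, 6, dimnames = list(NULL, paste0("s", 1:6)))
  groups <- rep(c("ATRX", "MYCN", "WT"), each = 2)
  st1 <- differential_occupancy(cnt, groups)
  st2 <- differential_occupancy(cnt[, c(2, 1, 3, 4, 6, 5)],
                                groups)
  expect_equal(st1$t_mycn, st2$t_mycn)
  expect_equal(st1$p_wt, st2$p_wt)
})

test_that("zero library size and undersized groups are rejected", {
  cnt <- matrix(0L, 5, 6, dimnames = list(NULL, paste0("s", 1:6)))
  expect_error(differential_occupancy(cnt, rep(c("ATRX", "MYCN", "WT"),
                                               each = 2)),
               "zero library size")
  cnt2 <- matrix(5L, 5, 5)
  expect_error(differential_occupancy(cnt2, c("ATRX", "ATRX", "MYCN",
                                              "MYCN", "WT")),
               ">= 2 samples")
})

test_that("presence patterns map to the C/E/D/O definitions", {
  pats <- expand.grid(ATRX = c(TRUE, FALSE), MYCN = c(TRUE, FALSE),
                      WT = c(TRUE, FALSE))
  ref <- interval_set("a", (seq_len(nrow(pats)) - 1) * 100,
                      (seq_len(nrow(pats)) - 1) * 100 + 50)
  S4Vectors::mcols(ref)$present_ATRX <- pats$ATRX
  S4Vectors::mcols(ref)$present_MYCN <- pats$MYCN
  S4Vectors::mcols(ref)$present_WT <- pats$WT
  lab <- as.character(S4Vectors::mcols(classify_peak_groups(ref))$label)
  want <- function(a, m, w) {
    if (a && m && w) "C" else if (a && !m && !w) "E"
    else if (!a && m && w) "D" else if (a && xor(m, w)) "O"
    else "unclassified"
  }
  expect_equal(lab, mapply(want, pats$ATRX, pats$MYCN, pats$WT,
                           USE.NAMES = FALSE))
  # every peak gets exactly one label; counts sum to the set size
  expect_equal(sum(table(lab)), nrow(pats))
})

test_that("stats-gated classification demotes non-significant E/D peaks", {
  ref <- interval_set("a", c(0, 100), c(50, 150))
  S4Vectors::mcols(ref)$present_ATRX <- c(TRUE, FALSE)
  S4Vectors::mcols(ref)$present_MYCN <- c(FALSE, TRUE)
  S4Vectors::mcols(ref)$present_WT <- c(FALSE, TRUE)
  st <- tibble::tibble(logFC_mycn = c(2, -2), adj_p_mycn = c(0.01, 0.5),
                       logFC_wt = c(2, -2), adj_p_wt = c(0.01, 0.5))
  lab <- S4Vectors::mcols(classify_peak_groups(ref, st,
                                               mode = "presence+stats"))$label
  expect_equal(as.character(lab), c("E", "unclassified"))
  expect_error(classify_peak_groups(ref, mode = "presence+stats"),
               "requires differential statistics")
})

test_that("zero-noise landscapes are recovered perfectly end to end", {
  b <- make_clean_bundle(seed = 29)
  res <- classify_landscape(b)
  pk <- b$truth$planted_peaks
  expect_equal(length(res$reference), nrow(pk))
  expect_equal(interval_start(res$reference), pk$start)
  expect_equal(as.character(S4Vectors::mcols(res$reference)$label), pk$label)
})

test_that("label recovery stays high at the default noise settings", {
  tr <- landscape_truth(n_per_label = c(C = 25, E = 25, D = 25, O = 25),
                        seed = 37)
  b <- simulate_peak_landscape(tr)  # default jitter and background
  res <- classify_landscape(b)
  ref <- res$reference
  pk <- tr$planted_peaks
  pgr <- interval_set(pk$seq, pk$start, pk$end)
  ov <- GenomicRanges::findOverlaps(ref, pgr, ignore.strand = TRUE)
  lab <- as.character(S4Vectors::mcols(ref)$label)[S4Vectors::queryHits(ov)]
  acc <- mean(lab == pk$label[S4Vectors::subjectHits(ov)])
  expect_gte(acc, 0.95)
})
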