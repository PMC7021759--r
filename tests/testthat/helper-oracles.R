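# Brute-force oracles, independent of the GRanges-backed implementation.
# All coordinates are 0-based half-open; overlap means >= 1 shared bp.

# Pairwise sweep union: sort by (seq, start); extend the open interval only
# on strict overlap (start < current end), so abutting intervals stay apart.
oracle_merge <- function(df) {
  df <- df[order(df$seq, df$start, df$end), ]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.null(cur) || row$seq != cur$seq || row$start >= cur$end) {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- row
    } else {
      cur$end <- max(cur$end, row$end)
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  do.call(rbind, out)
}

# All-pairs overlap flags for each query row.
oracle_overlap_hit <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(s$seq == q$seq[i] & s$start < q$end[i] & s$end > q$start[i])
  }, logical(1))
}

# Per-query count of overlapping subject rows.
oracle_overlap_count <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    sum(s$seq == q$seq[i] & s$start < q$end[i] & s$end > q$start[i])
  }, integer(1))
}

random_intervals_df <- function(n, seqs = c("a", "b"), max_pos = 5000,
                                max_width = 200) {
  start <- floor(runif(n, 0, max_pos))
  width <- pmax(1, floor(runif(n, 1, max_width)))
  data.frame(seq = sample(seqs, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) interval_set(df$seq, df$start, df$end)

gr_to_df <- function(gr) {
  data.frame(seq = as.character(GenomicRanges::seqnames(gr)),
             start = interval_start(gr), end = interval_end(gr),
             stringsAsFactors = FALSE)
}

# Exact two-sided binomial tail interval by bisection on the binomial CDF,
# used as an independent check of the beta-quantile Clopper-Pearson form.
oracle_clopper_pearson <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

# A small, fully in-memory landscape bundle used across test files.
make_clean_bundle <- function(seed = 11, n_per_label = c(C = 5, E = 5,
                                                         D = 5, O = 5)) {
  tr <- landscape_truth(n_per_label = n_per_label, seed = seed)
  simulate_peak_landscape(tr, jitter = 0, noise_rate = 0, low_only_rate = 0)
}
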