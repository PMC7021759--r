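#' Construct an interval set from 0-based half-open coordinates
#'
#' All genomic coordinates exchanged with the user and with BED-family files
#' follow the BED convention: 0-based starts, exclusive ends.  Internally
#' intervals are held as `GRanges` (1-based, closed), and every function in
#' this package converts at the boundary, so overlap and merge semantics are
#' exactly "at least one shared base pair; abutting intervals do not touch".
#'
#' @param seqnames character vector of sequence names.
#' @param start,end integer vectors; `0 <= start < end` (0-based half-open).
#' @param strand optional strand vector (`"+"`, `"-"`, `"*"`); default `"*"`.
#' @param ... further vectors stored as metadata columns.
#' @param provenance optional label (sample or track name) kept as metadata.
#' @return A `GRanges` object.
#' @examples
#' gr <- interval_set("chr1", c(0, 10), c(10, 20))
#' interval_width(gr)
#' @export
interval_set <- function(seqnames, start, end, strand = NULL, ...,
                         provenance = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval coordinates must be finite numbers")
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0))
    stop("negative start coordinate")
  if (any(start >= end))
    stop("interval start must be < end (0-based half-open)")
  if (any(!nzchar(seqnames)))
    stop("empty sequence name")
  if (is.null(strand)) strand <- "*"
  seqnames <- as.character(seqnames)
  # sorted seqlevels make merge/sort output independent of input order
  seqnames <- factor(seqnames, levels = sort(unique(seqnames)))
  gr <- GenomicRanges::GRanges(
    seqnames = seqnames,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  extra <- list(...)
  if (length(extra))
    S4Vectors::mcols(gr)[names(extra)] <- extra
  if (!is.null(provenance))
    S4Vectors::metadata(gr)$provenance <- provenance
  gr
}

#' 0-based starts / exclusive ends of an interval set
#'
#' @param x a `GRanges` object.
#' @return Integer vector of 0-based starts (`interval_start`), exclusive
#'   ends (`interval_end`), or widths (`interval_width`).
#' @export
interval_start <- function(x) GenomicRanges::start(x) - 1L

#' @rdname interval_start
#' @export
interval_end <- function(x) GenomicRanges::end(x)

#' @rdname interval_start
#' @export
interval_width <- function(x) GenomicRanges::width(x)

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read intervals from BED, narrowPeak or segmentation files
#'
#' Reads tab-separated interval files into a `GRanges`.  Lines starting with
#' `#`, `track` or `browser` are skipped.  Coordinates are validated
#' (integer, non-negative, start < end); malformed lines raise an error that
#' names the offending line numbers.
#'
#' Formats:
#' \describe{
#'   \item{bed}{columns 1--3 are seq/start/end; columns 4--6, when present,
#'     are kept as `name`, `score`, strand.}
#'   \item{narrowPeak}{BED6+4; columns 7--10 are kept as `signalValue`,
#'     `pValue`, `qValue`, `summit` metadata.}
#'   \item{segmentation}{column 4 is a ChromHMM-style state label, accepted
#'     as either a plain number (`"13"`) or an `E`-prefixed label (`"E13"`),
#'     stored as integer metadata column `state`.}
#' }
#'
#' @param path file path.
#' @param format one of `"bed"`, `"narrowPeak"`, `"segmentation"`.
#' @param provenance optional provenance label stored in metadata.
#' @return A `GRanges` object.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "segmentation"),
                           provenance = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(provenance)) S4Vectors::metadata(gr)$provenance <- provenance
    return(gr)
  }
  fields <- .split_fields(lines)
  ncols <- lengths(fields)
  min_cols <- switch(format, bed = 3L, narrowPeak = 10L, segmentation = 4L)
  bad <- lineno[ncols < min_cols]
  if (length(bad))
    stop(sprintf("%s: expected >= %d tab-separated columns on line(s) %s",
                 path, min_cols, paste(utils::head(bad, 5), collapse = ", ")))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  seqs <- col(1)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- lineno[is.na(start) | is.na(end) |
                start != floor(start) | end != floor(end)]
  if (length(bad))
    stop(sprintf("%s: non-integer coordinates on line(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  bad <- lineno[start < 0 | start >= end]
  if (length(bad))
    stop(sprintf("%s: invalid coordinates (need 0 <= start < end) on line(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  strand <- "*"
  extra <- list()
  if (format == "bed") {
    if (all(ncols >= 4)) extra$name <- col(4)
    if (all(ncols >= 5)) extra$score <- suppressWarnings(as.numeric(col(5)))
    if (all(ncols >= 6)) strand <- .parse_strand(col(6))
  } else if (format == "narrowPeak") {
    extra$name <- col(4)
    extra$score <- suppressWarnings(as.numeric(col(5)))
    strand <- .parse_strand(col(6))
    extra$signalValue <- suppressWarnings(as.numeric(col(7)))
    extra$pValue <- suppressWarnings(as.numeric(col(8)))
    extra$qValue <- suppressWarnings(as.numeric(col(9)))
    extra$summit <- suppressWarnings(as.integer(col(10)))
  } else { # segmentation
    lab <- sub("^[A-Za-z]+", "", col(4))
    state <- suppressWarnings(as.integer(lab))
    bad <- lineno[is.na(state)]
    if (length(bad))
      stop(sprintf("%s: unparseable state label on line(s) %s",
                   path, paste(utils::head(bad, 5), collapse = ", ")))
    extra$state <- state
  }
  gr <- do.call(interval_set,
                c(list(seqnames = seqs, start = start, end = end,
                       strand = strand, provenance = provenance),
                  extra))
  gr
}

.parse_strand <- function(x) {
  x[!x %in% c("+", "-")] <- "*"
  x
}

#' Write an interval set as BED
#'
#' Writes seq, 0-based start, exclusive end, and (when present) `name`,
#' `score` and strand columns, tab-separated, sorted as stored.
#'
#' @param x a `GRanges` object.
#' @param path output path.
#' @param extra_cols names of metadata columns to append after the strand
#'   column (used for segmentation state tracks).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = NULL) {
  df <- data.frame(
    seq = as.character(GenomicRanges::seqnames(x)),
    start = interval_start(x),
    end = interval_end(x),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(x)
  if (!is.null(extra_cols)) {
    df$name <- if ("name" %in% names(mc)) mc$name else "."
    df$score <- if ("score" %in% names(mc)) mc$score else 0
    df$strand <- as.character(GenomicRanges::strand(x))
    for (cn in extra_cols) df[[cn]] <- mc[[cn]]
  } else if ("name" %in% names(mc)) {
    df$name <- mc$name
    if ("score" %in% names(mc)) {
      df$score <- mc$score
      df$strand <- as.character(GenomicRanges::strand(x))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals
#'
#' Unions intervals that share at least one base pair.  Abutting intervals
#' (end of one equal to start of the next in 0-based half-open coordinates)
#' are \emph{not} merged.  Idempotent.
#'
#' @param x a `GRanges` object.
#' @param with_revmap if `TRUE`, attach a `revmap` metadata column listing,
#'   for each merged interval, the indices of the contributing input
#'   intervals.
#' @return A `GRanges` of disjoint intervals, sorted.
#' @examples
#' merge_intervals(interval_set("a", c(0, 5), c(10, 15)))   # one interval
#' merge_intervals(interval_set("a", c(0, 10), c(10, 20)))  # stays two
#' @export
merge_intervals <- function(x, with_revmap = FALSE) {
  out <- GenomicRanges::reduce(x, min.gapwidth = 0L,
                               with.revmap = with_revmap,
                               ignore.strand = TRUE)
  out
}

#' Overlap query between two interval sets
#'
#' A query interval is a hit iff some subject interval shares at least one
#' base pair with it.  Strand is ignored.
#'
#' @param query,subject `GRanges` objects.
#' @return A list with `hit` (logical per query interval) and `hits` (a list
#'   of integer vectors of subject indices per query interval).
#' @export
overlap_query <- function(query, subject) {
  al <- .align_seqlevels(query, subject)
  ov <- GenomicRanges::findOverlaps(al$x, al$y, minoverlap = 1L,
                                    ignore.strand = TRUE)
  hit <- rep(FALSE, length(query))
  qh <- S4Vectors::queryHits(ov)
  hit[unique(qh)] <- TRUE
  hits <- split(S4Vectors::subjectHits(ov), factor(qh, levels = seq_along(query)))
  list(hit = hit, hits = unname(as.list(hits)))
}

#' Count overlapping subject intervals per query interval
#'
#' @param query,subject `GRanges` objects.
#' @return Integer vector, one count per query interval.
#' @export
overlap_count <- function(query, subject) {
  al <- .align_seqlevels(query, subject)
  GenomicRanges::countOverlaps(al$x, al$y, minoverlap = 1L,
                               ignore.strand = TRUE)
}

# Give two GRanges a common (sorted) seqlevel universe so that overlap
# operations between tracks from different sequences stay silent.
.align_seqlevels <- function(x, y) {
  lev <- sort(union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(y)))
  GenomeInfoDb::seqlevels(x) <- lev
  GenomeInfoDb::seqlevels(y) <- lev
  list(x = x, y = y)
}

# Total bp of the query interval covered by each level of `by` among subject
# intervals; used for dominant-state and state-13 proportion computations.
.coverage_by <- function(query1, subject, by) {
  al <- .align_seqlevels(query1, subject)
  query1 <- al$x; subject <- al$y
  ov <- GenomicRanges::findOverlaps(query1, subject, minoverlap = 1L,
                                    ignore.strand = TRUE)
  sh <- S4Vectors::subjectHits(ov)
  if (!length(sh)) return(numeric(0))
  inter <- IRanges::pintersect(rep(query1, length(sh)), subject[sh],
                               ignore.strand = TRUE)
  w <- GenomicRanges::width(inter)
  tapply(w, by[sh], sum)
}
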