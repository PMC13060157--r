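#' Pearson product-moment correlation with a zero-variance guard
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return the coefficient, or `NA_real_` when either vector has zero
#'   variance (Pearson is undefined there).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 positions", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  # identical vectors are exactly 1 by definition; skip the floating trip
  if (identical(as.numeric(x), as.numeric(y))) return(1)
  cor(x, y)
}

#' Sliding-window sums
#'
#' Valid-mode sums of `k` consecutive elements (step 1), as used for the
#' coarser 5-nt-resolution correlation.
#'
#' @param x numeric vector with `length(x) >= k`.
#' @param k window size in nt (default 5).
#' @return numeric vector of length `length(x) - k + 1`.
#' @export
sliding_window_sum <- function(x, k = 5L) {
  n <- length(x)
  if (n < k) stop("vector shorter than window", call. = FALSE)
  if (k == 1L) return(as.numeric(x))
  cs <- cumsum(as.numeric(x))
  cs[k:n] - c(0, cs[seq_len(n - k)])
}

#' Reads-per-kilobase-per-million expression
#'
#' @param total_reads reads in the region.
#' @param window_length region length in nt.
#' @param library_size total reads in the library.
#' @return RPKM value `total / ((window_length/1000) * (library_size/1e6))`.
#' @export
rpkm <- function(total_reads, window_length, library_size) {
  if (window_length <= 0) stop("window_length must be > 0", call. = FALSE)
  if (library_size <= 0) stop("library_size must be > 0", call. = FALSE)
  total_reads / ((window_length / 1000) * (library_size / 1e6))
}

# counts for positions start..end-1 on (chrom, strand), 5'->3' for strand.
extract_window_counts <- function(lookup, chrom, strand, start, end) {
  n <- end - start
  v <- numeric(n)
  tab <- lookup[[paste(chrom, strand, sep = "\r")]]
  if (!is.null(tab)) {
    idx <- match(start:(end - 1L), tab$pos)
    hit <- !is.na(idx)
    v[hit] <- tab$count[idx[hit]]
  }
  if (strand == "-") rev(v) else v
}

track_lookup <- function(track) {
  split(track$counts[c("pos", "count")],
        paste(track$counts$chrom, track$counts$strand, sep = "\r"))
}

#' Per-transcript TSS concordance between two 5'-end tracks
#'
#' For each TSS-centred window, extracts strand-matched per-position counts
#' from both raw tracks (read 5'->3' relative to the transcript strand),
#' computes window totals, each track's RPKM (window length as the length
#' denominator, each track's own library size), and Pearson correlations at
#' 1-nt resolution and on 5-nt sliding-window sums. Records where either
#' track's RPKM falls below `min_rpkm` are dropped; zero-variance windows
#' are retained but flagged `valid = FALSE`.
#'
#' @param track_a,track_b raw [five_prime_track()] objects.
#' @param models list of [transcript_model()] objects.
#' @param flank half-window in nt (default 500, i.e. 1001-nt windows).
#' @param k sliding-window size for the coarse correlation (default 5).
#' @param min_rpkm expression filter threshold applied to both tracks
#'   (default 1).
#' @param chrom_lengths optional named vector for window edge clipping.
#' @return data.frame with one row per retained window: `transcript_id`
#'   (comma-joined when isoforms share a TSS), `chrom`, `strand`, `tss`,
#'   `total_a`, `total_b`, `rpkm_a`, `rpkm_b`, `r_1nt`, `r_5nt`, `valid`.
#' @export
concordance_table <- function(track_a, track_b, models, flank = 500L, k = 5L,
                              min_rpkm = 1, chrom_lengths = NULL) {
  stopifnot(inherits(track_a, "five_prime_track"),
            inherits(track_b, "five_prime_track"))
  if (track_a$scale != "raw" || track_b$scale != "raw") {
    stop("concordance_table needs raw-scale tracks (library sizes required)",
         call. = FALSE)
  }
  win <- tss_windows(models, flank = flank, chrom_lengths = chrom_lengths)
  la <- track_lookup(track_a)
  lb <- track_lookup(track_b)
  wlen <- 2L * as.integer(flank) + 1L
  rows <- lapply(seq_len(nrow(win)), function(i) {
    a <- extract_window_counts(la, win$chrom[i], win$strand[i], win$start[i],
                               win$end[i])
    b <- extract_window_counts(lb, win$chrom[i], win$strand[i], win$start[i],
                               win$end[i])
    ra <- rpkm(sum(a), wlen, track_a$library_size)
    rb <- rpkm(sum(b), wlen, track_b$library_size)
    if (min(ra, rb) < min_rpkm) return(NULL)
    r1 <- pearson_r(a, b)
    r5 <- pearson_r(sliding_window_sum(a, k), sliding_window_sum(b, k))
    data.frame(transcript_id = paste(win$transcript_ids[[i]], collapse = ","),
               chrom = win$chrom[i], strand = win$strand[i], tss = win$tss[i],
               total_a = sum(a), total_b = sum(b), rpkm_a = ra, rpkm_b = rb,
               r_1nt = r1, r_5nt = r5, valid = !is.na(r1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), chrom = character(0),
                      strand = character(0), tss = integer(0),
                      total_a = numeric(0), total_b = numeric(0),
                      rpkm_a = numeric(0), rpkm_b = numeric(0),
                      r_1nt = numeric(0), r_5nt = numeric(0),
                      valid = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Summarize concordance by expression bin
#'
#' Invalid (zero-variance) records are excluded; the remaining records are
#' binned by `log10` of the mean of the two window totals and the
#' per-bin count, median and quartiles of `r_1nt` (and `r_5nt`) reported.
#'
#' @param records output of [concordance_table()].
#' @param bins number of equal-width log10 bins (default 3) or a vector of
#'   bin edges on the log10 mean-total scale.
#' @return data.frame with `bin`, `lower`, `upper` (log10 edges), `n`,
#'   `median_r`, `q1_r`, `q3_r`, `median_r5`.
#' @export
summarize_by_expression <- function(records, bins = 3L) {
  stopifnot(nrow(records) > 0)
  rec <- records[records$valid, , drop = FALSE]
  if (nrow(rec) == 0) stop("no valid records after exclusions", call. = FALSE)
  x <- log10((rec$total_a + rec$total_b) / 2)
  edges <- if (length(bins) == 1L) {
    seq(min(x), max(x), length.out = bins + 1L)
  } else sort(bins)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(edges) - 1L
  out <- lapply(seq_len(nb), function(b) {
    r <- rec$r_1nt[idx == b]
    r5 <- rec$r_5nt[idx == b]
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               n = length(r),
               median_r = if (length(r)) median(r) else NA_real_,
               q1_r = if (length(r)) unname(quantile(r, 0.25)) else NA_real_,
               q3_r = if (length(r)) unname(quantile(r, 0.75)) else NA_real_,
               median_r5 = if (length(r5)) median(r5, na.rm = TRUE) else NA_real_)
  })
  do.call(rbind, out)
}
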