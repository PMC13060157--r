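#' Construct a set of spliced alignments
#'
#' Lightweight container for the parts of a spliced alignment the pipeline
#' needs: strand, ordered aligned blocks (0-based half-open) and the primary
#' flag. Alignment itself is performed externally; see [read_alignments()]
#' for BAM input.
#'
#' @param read_id character vector of read identifiers.
#' @param chrom chromosome per alignment.
#' @param strand `"+"`/`"-"` per alignment.
#' @param blocks list of 2-column matrices (`start`, `end`; 0-based
#'   half-open, sorted, non-overlapping), one per alignment.
#' @param is_primary logical per alignment (recycled).
#' @return data.frame of class `alignment_set` with a `blocks` list-column.
#' @export
alignment_set <- function(read_id, chrom, strand, blocks, is_primary = TRUE) {
  n <- length(read_id)
  stopifnot(length(chrom) == n, length(strand) == n, length(blocks) == n,
            all(strand %in% c("+", "-")))
  for (b in blocks) {
    if (!is.matrix(b) || ncol(b) != 2 || nrow(b) < 1) {
      stop("each blocks entry must be a 2-column matrix with >= 1 row",
           call. = FALSE)
    }
    if (any(b[, 1] >= b[, 2])) stop("blocks must satisfy start < end", call. = FALSE)
    if (nrow(b) > 1 && any(b[-1, 1] < b[-nrow(b), 2])) {
      stop("blocks must be sorted and non-overlapping", call. = FALSE)
    }
  }
  out <- data.frame(read_id = as.character(read_id), chrom = as.character(chrom),
                    strand = strand,
                    is_primary = rep_len(is_primary, n),
                    stringsAsFactors = FALSE)
  out$blocks <- blocks
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Read spliced alignments from a BAM file
#'
#' Imports primary (and optionally secondary) alignments with their aligned
#' blocks, via GenomicAlignments.
#'
#' @param path BAM file path.
#' @param primary_only drop secondary and supplementary alignments.
#' @return an [alignment_set()].
#' @export
read_alignments <- function(path, primary_only = TRUE) {
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (primary_only) FALSE else NA,
    isSupplementaryAlignment = if (primary_only) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "flag"))
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  blk <- GenomicAlignments::grglist(ga)
  blocks <- lapply(seq_along(ga), function(i) {
    r <- blk[[i]]
    b <- cbind(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
    # grglist returns 5'->3' order; alignment_set wants genomic order
    b[order(b[, 1]), , drop = FALSE]
  })
  flags <- S4Vectors::mcols(ga)$flag
  alignment_set(read_id = S4Vectors::mcols(ga)$qname,
                chrom = as.character(GenomicAlignments::seqnames(ga)),
                strand = as.character(BiocGenerics::strand(ga)),
                blocks = blocks,
                is_primary = bitwAnd(flags, 0x900) == 0L)
}

#' Construct a strand-specific 5'-end track
#'
#' Sparse per-base counts of read 5' ends, keyed by chromosome, strand and
#' 0-based position, together with the library size and a scale flag.
#'
#' @param counts data.frame with `chrom`, `strand`, `pos` (0-based) and
#'   `count` (> 0); duplicate positions are summed.
#' @param library_size total number of 5' ends the track derives from.
#' @param scale `"raw"` or `"RPM"`.
#' @return object of class `five_prime_track`.
#' @export
five_prime_track <- function(counts, library_size, scale = c("raw", "RPM")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(counts),
            all(c("chrom", "strand", "pos", "count") %in% names(counts)))
  if (any(counts$count <= 0)) stop("counts must be positive", call. = FALSE)
  key <- paste(counts$chrom, counts$strand, counts$pos, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(counts$count, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    counts <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                         strand = vapply(parts, `[`, "", 2L),
                         pos = as.integer(vapply(parts, `[`, "", 3L)),
                         count = agg[, 1], stringsAsFactors = FALSE)
  }
  o <- order(counts$chrom, counts$strand, counts$pos)
  counts <- counts[o, c("chrom", "strand", "pos", "count")]
  rownames(counts) <- NULL
  # a raw track restricted to a region may hold fewer ends than the library,
  # never more; genome-wide tracks satisfy equality (tested downstream)
  if (scale == "raw" &&
      sum(counts$count) > library_size * (1 + 1e-9)) {
    stop("raw track: sum of counts cannot exceed library_size", call. = FALSE)
  }
  structure(list(counts = counts, library_size = as.integer(library_size),
                 scale = scale),
            class = "five_prime_track")
}

#' @export
print.five_prime_track <- function(x, ...) {
  cat(sprintf("<five_prime_track> %d position(s), library_size %d, scale %s\n",
              nrow(x$counts), x$library_size, x$scale))
  invisible(x)
}

#' Build a raw 5'-end track from alignments
#'
#' For each retained alignment the count at the read's 5'-most genomic base
#' is incremented: the first base of the first block on `+`, the last base
#' (`end - 1`) of the last block on `-`. The result is order-independent and
#' its counts sum to the number of retained alignments.
#'
#' @param alignments an [alignment_set()].
#' @param primary_only retain only primary alignments (default).
#' @return a raw [five_prime_track()].
#' @export
five_prime_ends <- function(alignments, primary_only = TRUE) {
  stopifnot(inherits(alignments, "alignment_set"))
  keep <- if (primary_only) alignments$is_primary else rep(TRUE, nrow(alignments))
  aln <- alignments[keep, , drop = FALSE]
  if (nrow(aln) == 0) {
    return(five_prime_track(
      data.frame(chrom = character(0), strand = character(0),
                 pos = integer(0), count = numeric(0)),
      library_size = 0L))
  }
  pos <- vapply(seq_len(nrow(aln)), function(i) {
    b <- aln$blocks[[i]]
    if (nrow(b) == 0) stop("alignment with empty blocks", call. = FALSE)
    if (aln$strand[i] == "+") b[1, 1] else b[nrow(b), 2] - 1L
  }, numeric(1))
  df <- data.frame(chrom = aln$chrom, strand = aln$strand,
                   pos = as.integer(pos), stringsAsFactors = FALSE)
  o <- do.call(order, df)
  df <- df[o, , drop = FALSE]
  new <- !duplicated(df)
  df2 <- df[new, , drop = FALSE]
  df2$count <- as.numeric(tabulate(cumsum(new)))
  five_prime_track(df2, library_size = nrow(aln), scale = "raw")
}

#' Rescale a raw track to reads per million
#'
#' @param track a raw [five_prime_track()] with `library_size > 0`.
#' @return the track with every count multiplied by `1e6 / library_size`
#'   and `scale = "RPM"`.
#' @export
to_rpm <- function(track) {
  stopifnot(inherits(track, "five_prime_track"))
  if (track$scale == "RPM") stop("track is already RPM-scaled", call. = FALSE)
  if (track$library_size == 0) stop("library_size is 0", call. = FALSE)
  track$counts$count <- track$counts$count * 1e6 / track$library_size
  track$scale <- "RPM"
  track
}

#' Write / read a 5'-end track as strand-split bedGraph files
#'
#' Two 4-column bedGraph files, `<prefix>.plus.bedGraph` and
#' `<prefix>.minus.bedGraph` (0-based half-open single-base intervals),
#' written through rtracklayer. The library size and scale are stored in a
#' small `<prefix>.meta.tsv` sidecar so raw tracks round-trip.
#'
#' @param track a [five_prime_track()].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_track_bedgraph <- function(track, prefix) {
  stopifnot(inherits(track, "five_prime_track"))
  for (s in c("+", "-")) {
    cnt <- track$counts[track$counts$strand == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = if (nrow(cnt)) cnt$chrom else character(0),
      ranges = IRanges::IRanges(start = cnt$pos + 1L, width = 1L),
      score = cnt$count)
    f <- paste0(prefix, if (s == "+") ".plus.bedGraph" else ".minus.bedGraph")
    rtracklayer::export(gr, f, format = "bedGraph")
  }
  meta <- data.frame(library_size = track$library_size, scale = track$scale)
  write.table(meta, paste0(prefix, ".meta.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(prefix)
}

#' @rdname write_track_bedgraph
#' @param prefix path prefix used by [write_track_bedgraph()].
#' @export
read_track_bedgraph <- function(prefix) {
  pieces <- lapply(c("+", "-"), function(s) {
    f <- paste0(prefix, if (s == "+") ".plus.bedGraph" else ".minus.bedGraph")
    gr <- rtracklayer::import(f, format = "bedGraph")
    if (length(gr) == 0) return(NULL)
    # bedGraph intervals may span several bases; expand to single-base counts
    w <- BiocGenerics::width(gr)
    data.frame(
      chrom = rep(as.character(GenomicAlignments::seqnames(gr)), w),
      strand = s,
      pos = unlist(mapply(function(s0, wd) seq.int(s0, length.out = wd),
                          BiocGenerics::start(gr) - 1L, w, SIMPLIFY = FALSE)),
      count = rep(S4Vectors::mcols(gr)$score, w),
      stringsAsFactors = FALSE)
  })
  meta <- read.delim(paste0(prefix, ".meta.tsv"))
  five_prime_track(do.call(rbind, pieces), library_size = meta$library_size,
                   scale = meta$scale)
}
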