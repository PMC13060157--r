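#' Construct a transcript model
#'
#' Exon structure of an annotated transcript. The TSS is derived (start of
#' the first exon on `+`, `end - 1` of the last exon on `-`) and the intron
#' chain is the ordered list of gaps between consecutive exons.
#'
#' @param transcript_id transcript identifier.
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column matrix (`start`, `end`; 0-based half-open, sorted,
#'   non-overlapping).
#' @return object of class `transcript_model` with derived `tss` and
#'   `introns` (2-column matrix, possibly 0 rows).
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.matrix(exons), ncol(exons) == 2, nrow(exons) >= 1,
            all(exons[, 1] < exons[, 2]))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  dimnames(exons) <- list(NULL, c("start", "end"))
  storage.mode(exons) <- "integer"
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    stop("exons must be non-overlapping with gaps between them", call. = FALSE)
  }
  introns <- if (nrow(exons) > 1) {
    cbind(start = unname(exons[-nrow(exons), 2]), end = unname(exons[-1, 1]))
  } else {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  tss <- if (strand == "+") exons[1, 1] else exons[nrow(exons), 2] - 1L
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, exons = exons, introns = introns,
                 tss = as.integer(tss)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d strand %s, %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$exons[1, 1],
              x$exons[nrow(x$exons), 2], x$strand, nrow(x$exons)))
  invisible(x)
}

#' Read transcript models from a GTF file
#'
#' Groups `exon` features by `transcript_id` via rtracklayer.
#'
#' @param path GTF file.
#' @return list of [transcript_model()] objects.
#' @export
read_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else tid
  idx <- split(seq_along(gr), tid)
  lapply(names(idx), function(t) {
    i <- idx[[t]]
    transcript_model(
      transcript_id = t, gene_id = gid[i[1]],
      chrom = as.character(GenomicAlignments::seqnames(gr))[i[1]],
      strand = as.character(BiocGenerics::strand(gr))[i[1]],
      exons = cbind(start = BiocGenerics::start(gr)[i] - 1L,
                    end = BiocGenerics::end(gr)[i]))
  })
}

#' Single-exon models matching a set of TSS profiles
#'
#' Convenience bridge from the synthetic world to the annotation-facing
#' analyses: each profile's dominant (modal) start becomes the annotated
#' TSS and the body runs to the profile's `tx_end`.
#'
#' @param profiles list of [tss_profile()] objects.
#' @return list of [transcript_model()] objects.
#' @export
models_from_profiles <- function(profiles) {
  if (inherits(profiles, "tss_profile")) profiles <- list(profiles)
  lapply(profiles, function(p) {
    tss <- as.integer(names(p$weights)[which.max(p$weights)])
    ex <- if (p$strand == "+") c(tss, p$tx_end + 1L) else c(p$tx_end, tss + 1L)
    transcript_model(p$transcript_id, p$transcript_id, p$chrom, p$strand,
                     matrix(ex, ncol = 2, dimnames = list(NULL, c("start", "end"))))
  })
}

#' TSS-centred windows for concordance analysis
#'
#' One window per distinct (chrom, strand, TSS) triple, spanning
#' `tss - flank .. tss + flank` (so `2*flank + 1` positions, including the
#' TSS base). Isoforms sharing a TSS collapse to one window carrying all
#' their transcript ids. Windows clipped by a contig edge are excluded
#' (flagged in the `n_excluded` attribute).
#'
#' @param models list of [transcript_model()] objects.
#' @param flank half-window size in nt (default 500).
#' @param chrom_lengths optional named vector for upper-edge clipping checks.
#' @return data.frame with `chrom`, `strand`, `tss`, `start`, `end`
#'   (0-based half-open) and a `transcript_ids` list-column; attribute
#'   `n_excluded` counts clipped windows.
#' @export
tss_windows <- function(models, flank = 500L, chrom_lengths = NULL) {
  stopifnot(flank > 0, length(models) > 0)
  flank <- as.integer(flank)
  df <- data.frame(
    chrom = vapply(models, `[[`, character(1), "chrom"),
    strand = vapply(models, `[[`, character(1), "strand"),
    tss = vapply(models, `[[`, integer(1), "tss"),
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    stringsAsFactors = FALSE)
  key <- paste(df$chrom, df$strand, df$tss, sep = "\r")
  ids <- split(df$transcript_id, key)
  first <- !duplicated(key)
  out <- df[first, c("chrom", "strand", "tss"), drop = FALSE]
  out$start <- out$tss - flank
  out$end <- out$tss + flank + 1L
  out$transcript_ids <- unname(ids[key[first]])
  ok <- out$start >= 0
  if (!is.null(chrom_lengths)) {
    ok <- ok & out$end <= chrom_lengths[out$chrom]
  }
  n_excl <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  out
}
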