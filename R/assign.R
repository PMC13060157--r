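# Intron intervals of an alignment: gaps between consecutive blocks.
alignment_introns <- function(blocks) {
  if (nrow(blocks) < 2) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = blocks[-nrow(blocks), 2], end = blocks[-1, 1])
}

# Is `ri` (read introns) a contiguous sub-chain of `mi` (model introns),
# with both ends of every junction within +/- tol?
chain_matches <- function(ri, mi, tol) {
  nr <- nrow(ri); nm <- nrow(mi)
  if (nr == 0) return(TRUE)
  if (nr > nm) return(FALSE)
  for (off in 0:(nm - nr)) {
    seg <- mi[off + seq_len(nr), , drop = FALSE]
    if (all(abs(seg[, 1] - ri[, 1]) <= tol) &&
        all(abs(seg[, 2] - ri[, 2]) <= tol)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Assign reads to transcript models by intron chain
#'
#' A read is compatible with a model iff it aligns to the same chromosome
#' and strand, every read intron matches a model intron within
#' `junction_tolerance` at both ends, the read introns form a contiguous
#' sub-chain of the model's chain, and all read blocks lie within the
#' model's exonic span. Mono-exonic reads are compatible when contained in
#' the exonic span without overlapping any model intron. A read compatible
#' with `k` models contributes `1/k` to each (fractional assignment);
#' incompatible reads are counted as unassigned.
#'
#' @param alignments an [alignment_set()].
#' @param models list of [transcript_model()] objects.
#' @param junction_tolerance per-junction-end slack in nt (default 0).
#' @return list with `counts` (data.frame `transcript_id`, `count`,
#'   `percent` of assigned reads), `n_assigned`, `n_unassigned` and
#'   `assignments` (per-read list of compatible transcript ids).
#' @export
assign_to_models <- function(alignments, models, junction_tolerance = 0L) {
  stopifnot(inherits(alignments, "alignment_set"), length(models) > 0)
  tol <- as.integer(junction_tolerance)
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  counts <- setNames(numeric(length(models)), ids)
  assignments <- vector("list", nrow(alignments))
  n_unassigned <- 0L
  for (i in seq_len(nrow(alignments))) {
    blocks <- alignments$blocks[[i]]
    ri <- alignment_introns(blocks)
    hits <- character(0)
    for (m in models) {
      if (m$chrom != alignments$chrom[i] || m$strand != alignments$strand[i]) next
      span <- c(m$exons[1, 1], m$exons[nrow(m$exons), 2])
      if (blocks[1, 1] < span[1] || blocks[nrow(blocks), 2] > span[2]) next
      if (nrow(ri) == 0) {
        # mono-exonic: containment and no model intron overlapped
        if (nrow(m$introns) > 0 &&
            any(m$introns[, 1] < blocks[1, 2] & m$introns[, 2] > blocks[1, 1])) next
        hits <- c(hits, m$transcript_id)
      } else if (chain_matches(ri, m$introns, tol)) {
        hits <- c(hits, m$transcript_id)
      }
    }
    assignments[[i]] <- hits
    if (length(hits) == 0) {
      n_unassigned <- n_unassigned + 1L
    } else {
      counts[hits] <- counts[hits] + 1 / length(hits)
    }
  }
  n_assigned <- nrow(alignments) - n_unassigned
  out <- data.frame(transcript_id = ids, count = unname(counts),
                    percent = if (n_assigned > 0) {
                      100 * unname(counts) / n_assigned
                    } else rep(NA_real_, length(ids)),
                    stringsAsFactors = FALSE)
  list(counts = out, n_assigned = n_assigned, n_unassigned = n_unassigned,
       assignments = assignments)
}
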