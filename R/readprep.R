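#' Adapter specification for full-length read selection
#'
#' Defaults mirror the cited trimming step: the 21-nt template-switching
#' oligo (TSO), a minimum adapter overlap of 15 nt and a 10% error rate, and
#' a polyA definition of at least 8 A's with at most 1 non-A base.
#'
#' @param tso_sequence TSO sequence expected at the sense 5' end.
#' @param min_overlap minimum matched adapter length (nt).
#' @param max_error_rate maximum edit-distance fraction of the matched
#'   adapter length (`floor(max_error_rate * overlap)` errors allowed).
#' @param polya_min_run minimum polyA run length (nt).
#' @param polya_max_mismatches non-A bases tolerated inside a run.
#' @return object of class `adapter_spec`.
#' @export
adapter_spec <- function(tso_sequence = "CAATGAAGTCGCAGGGTTGGG",
                         min_overlap = 15L, max_error_rate = 0.1,
                         polya_min_run = 8L, polya_max_mismatches = 1L) {
  check_dna(tso_sequence, "tso_sequence")
  if (nchar(tso_sequence) < min_overlap) {
    stop("tso_sequence must be at least min_overlap long", call. = FALSE)
  }
  stopifnot_scalar_number(max_error_rate, "max_error_rate", 0, 0.5 - 1e-12)
  stopifnot_scalar_number(min_overlap, "min_overlap", lower = 1)
  stopifnot_scalar_number(polya_min_run, "polya_min_run", lower = 1)
  stopifnot_scalar_number(polya_max_mismatches, "polya_max_mismatches", lower = 0)
  structure(list(tso_sequence = tso_sequence,
                 min_overlap = as.integer(min_overlap),
                 max_error_rate = max_error_rate,
                 polya_min_run = as.integer(polya_min_run),
                 polya_max_mismatches = as.integer(polya_max_mismatches)),
            class = "adapter_spec")
}

# Best valid candidate for one orientation, or NULL.
# Sense: full adapter anywhere, or an adapter *suffix* (>= min_overlap)
# anchored at the read start. Candidate ranking: lower edit distance, then
# 5'-most span start, then larger overlap, then smaller span end.
best_sense_match <- function(seq, spec) {
  m <- nchar(spec$tso_sequence)
  cands <- list()
  full <- adapter_scan_full(seq, spec$tso_sequence)
  if (!is.na(full[1]) && full[1] <= floor(spec$max_error_rate * m)) {
    cands[[length(cands) + 1L]] <-
      list(dist = full[1], start = full[2], end = full[3], overlap = m)
  }
  part <- adapter_scan_start(seq, spec$tso_sequence, spec$min_overlap,
                             spec$max_error_rate)
  if (!is.na(part[1])) {
    cands[[length(cands) + 1L]] <-
      list(dist = part[1], start = 0L, end = part[3], overlap = part[2])
  }
  if (length(cands) == 0) return(NULL)
  ord <- order(vapply(cands, `[[`, integer(1), "dist"),
               vapply(cands, `[[`, integer(1), "start"),
               -vapply(cands, `[[`, integer(1), "overlap"),
               vapply(cands, `[[`, integer(1), "end"))
  cands[[ord[1]]]
}

#' Locate the template-switching oligo in a read
#'
#' Error-tolerant semi-global search for the TSO near the read 5' end
#' (sense) or for its reverse complement near the 3' end (antisense).
#' A match needs overlap >= `min_overlap` and edit distance <=
#' `floor(max_error_rate * overlap)`; indels are allowed and `N` never
#' matches. Ties are broken by lower edit distance, then sense over
#' antisense, then the 5'-most span.
#'
#' @param read a read sequence (character scalar) or a list/row with
#'   `sequence`.
#' @param spec an [adapter_spec()].
#' @return list with `orientation` (`"sense"`, `"antisense"` or `"none"`),
#'   `start`/`end` (0-based half-open span on the read as given),
#'   `edit_distance`, `overlap`, and `both_orientations` (chimera flag:
#'   valid matches found in both orientations).
#' @export
locate_tso <- function(read, spec = adapter_spec()) {
  seq <- if (is.character(read)) read else read$sequence
  stopifnot(length(seq) == 1L, nzchar(seq))
  n <- nchar(seq)
  sense <- best_sense_match(seq, spec)
  # Antisense: mirror the search on the reverse-complemented read, then map
  # coordinates back.
  rseq <- revcomp_cpp(seq)
  anti <- best_sense_match(rseq, spec)
  if (!is.null(anti)) {
    anti <- list(dist = anti$dist, start = n - anti$end, end = n - anti$start,
                 overlap = anti$overlap)
  }
  none <- list(orientation = "none", start = NA_integer_, end = NA_integer_,
               edit_distance = NA_integer_, overlap = NA_integer_,
               both_orientations = FALSE)
  if (is.null(sense) && is.null(anti)) return(none)
  both <- !is.null(sense) && !is.null(anti)
  pick_sense <- !is.null(sense) && (is.null(anti) || sense$dist <= anti$dist)
  hit <- if (pick_sense) sense else anti
  list(orientation = if (pick_sense) "sense" else "antisense",
       start = as.integer(hit$start), end = as.integer(hit$end),
       edit_distance = as.integer(hit$dist), overlap = as.integer(hit$overlap),
       both_orientations = both)
}

#' Detect a polyA (or 5' polyT) run
#'
#' Searches the terminal 50 nt of the sequence for the 3'-most run of at
#' least `polya_min_run` A's containing at most `polya_max_mismatches` non-A
#' bases (runs must begin and end with A; `N` counts as a mismatch). With
#' `end = "5T"` the symmetric search for a polyT run in the first 50 nt is
#' performed, as antisense evidence.
#'
#' @param seq nucleotide string.
#' @param spec an [adapter_spec()].
#' @param end `"3A"` (default) or `"5T"`.
#' @return list with 1-based `start`, `end` (inclusive) and `length`, or
#'   `NULL` when no run qualifies.
#' @export
detect_polya <- function(seq, spec = adapter_spec(), end = c("3A", "5T")) {
  end <- match.arg(end)
  stopifnot(length(seq) == 1L, nzchar(seq))
  n <- nchar(seq)
  w <- min(50L, n)
  if (end == "3A") {
    window <- substr(seq, n - w + 1L, n)
    hit <- polya_scan(window, "A", spec$polya_min_run, spec$polya_max_mismatches)
    if (is.na(hit[1])) return(NULL)
    start <- (n - w) + hit[1] + 1L
    stop_ <- (n - w) + hit[2]
  } else {
    # Mirror: reverse the leading window and look for the "3'-most" T run,
    # which maps back to the 5'-most run of the original.
    window <- paste(rev(strsplit(substr(seq, 1L, w), "")[[1]]), collapse = "")
    hit <- polya_scan(window, "T", spec$polya_min_run, spec$polya_max_mismatches)
    if (is.na(hit[1])) return(NULL)
    start <- w - hit[2] + 1L
    stop_ <- w - hit[1]
  }
  list(start = as.integer(start), end = as.integer(stop_),
       length = as.integer(stop_ - start + 1L))
}

#' Select and orient full-length reads
#'
#' The full-length selection step: reads without a TSO match in either
#' orientation are discarded ("trimmed-only" behaviour); reads whose best
#' match is antisense are reverse-complemented; reads with valid matches in
#' both orientations are treated as chimeric and discarded. The TSO (and
#' anything 5' of it) is trimmed; polyA is detected on the sense sequence
#' and recorded as metadata but never trimmed.
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param spec an [adapter_spec()].
#' @return list with `reads` (data.frame `id`, `sense_sequence`,
#'   `was_reverse_complemented`, `tso_edit_distance`, `polya_site` 1-based
#'   start of the detected polyA run or `NA`) and `report` (single-row
#'   data.frame: `n_input`, `n_kept`, `n_discarded_no_tso`, `n_chimeric`,
#'   `n_reverse_complemented`, `n_polya_detected`).
#' @export
select_full_length <- function(reads, spec = adapter_spec()) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  bad <- !nzchar(reads$sequence) | grepl("[^ACGTN]", reads$sequence)
  if (any(bad)) {
    stop(sprintf("unreadable record: %s", reads$id[which(bad)[1]]),
         call. = FALSE)
  }
  rseqs <- if (n > 0) revcomp_cpp(reads$sequence) else character(0)
  keep_id <- character(n); sense_seq <- character(n)
  was_rc <- logical(n); dist <- integer(n); polya <- integer(n)
  kept <- 0L; n_no_tso <- 0L; n_chim <- 0L
  for (i in seq_len(n)) {
    seq <- reads$sequence[i]
    len <- nchar(seq)
    sense <- best_sense_match(seq, spec)
    anti <- best_sense_match(rseqs[i], spec)
    if (is.null(sense) && is.null(anti)) { n_no_tso <- n_no_tso + 1L; next }
    if (!is.null(sense) && !is.null(anti)) { n_chim <- n_chim + 1L; next }
    if (!is.null(sense)) {
      ss <- substr(seq, sense$end + 1L, len)
      rc <- FALSE
      d <- sense$dist
    } else {
      ss <- substr(rseqs[i], anti$end + 1L, len)
      rc <- TRUE
      d <- anti$dist
    }
    if (!nzchar(ss)) { n_no_tso <- n_no_tso + 1L; next }
    pa <- detect_polya(ss, spec)
    kept <- kept + 1L
    keep_id[kept] <- reads$id[i]
    sense_seq[kept] <- ss
    was_rc[kept] <- rc
    dist[kept] <- d
    polya[kept] <- if (is.null(pa)) NA_integer_ else pa$start
  }
  idx <- seq_len(kept)
  out <- data.frame(id = keep_id[idx], sense_sequence = sense_seq[idx],
                    was_reverse_complemented = was_rc[idx],
                    tso_edit_distance = dist[idx], polya_site = polya[idx],
                    stringsAsFactors = FALSE)
  report <- data.frame(n_input = n, n_kept = nrow(out),
                       n_discarded_no_tso = n_no_tso, n_chimeric = n_chim,
                       n_reverse_complemented = sum(was_rc[idx]),
                       n_polya_detected = sum(!is.na(polya[idx])))
  list(reads = out, report = report)
}
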