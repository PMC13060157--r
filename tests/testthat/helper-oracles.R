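# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: direct formulas and exhaustive enumeration, sharing no
# code path with the package implementations they check.

# Pearson correlation by the raw product-moment formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive anchored adapter search, by enumerating candidate substrings and
# scoring each with utils::adist (plain Levenshtein; inputs must be N-free).
# Semantics mirror the documented locate_tso contract:
#   sense: full adapter at any substring, or an adapter suffix (length >=
#   min_overlap) anchored at the read start; ranking (dist, start, -overlap,
#   end). Antisense: the same search on the reverse complement, spans mapped
#   back. Orientation tie at equal distance goes to sense.
oracle_candidates <- function(text, pat, min_overlap, rate) {
  n <- nchar(text)
  m <- nchar(pat)
  cands <- list()
  allowed <- floor(rate * m)
  subs <- character(0)
  meta <- list()
  for (s in 0:(n - 1)) {
    for (len in max(1, m - allowed):(m + allowed)) {
      e <- s + len
      if (e > n) next
      subs <- c(subs, substr(text, s + 1, e))
      meta[[length(meta) + 1]] <- c(s, e)
    }
  }
  if (length(subs)) {
    d <- as.integer(adist(pat, subs))
    for (i in seq_along(subs)) {
      if (d[i] <= allowed) {
        cands[[length(cands) + 1]] <-
          list(dist = d[i], start = meta[[i]][1], end = meta[[i]][2], overlap = m)
      }
    }
  }
  for (L in min_overlap:(m - 1)) {
    al <- floor(rate * L)
    p <- substr(pat, m - L + 1, m)
    for (e in max(1, L - al):min(n, L + al)) {
      d <- as.integer(adist(p, substr(text, 1, e)))
      if (d <= al) {
        cands[[length(cands) + 1]] <-
          list(dist = d, start = 0L, end = e, overlap = L)
      }
    }
  }
  cands
}

oracle_best <- function(cands) {
  if (length(cands) == 0) return(NULL)
  ord <- order(vapply(cands, `[[`, numeric(1), "dist"),
               vapply(cands, `[[`, numeric(1), "start"),
               -vapply(cands, `[[`, numeric(1), "overlap"),
               vapply(cands, `[[`, numeric(1), "end"))
  cands[[ord[1]]]
}

oracle_locate_tso <- function(seq, spec) {
  n <- nchar(seq)
  sense <- oracle_best(oracle_candidates(seq, spec$tso_sequence,
                                         spec$min_overlap, spec$max_error_rate))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  anti <- oracle_best(oracle_candidates(rc, spec$tso_sequence,
                                        spec$min_overlap, spec$max_error_rate))
  if (!is.null(anti)) {
    anti <- list(dist = anti$dist, start = n - anti$end, end = n - anti$start,
                 overlap = anti$overlap)
  }
  if (is.null(sense) && is.null(anti)) {
    return(list(orientation = "none"))
  }
  pick_sense <- !is.null(sense) && (is.null(anti) || sense$dist <= anti$dist)
  hit <- if (pick_sense) sense else anti
  list(orientation = if (pick_sense) "sense" else "antisense",
       start = hit$start, end = hit$end, edit_distance = hit$dist)
}

# Exhaustive polyA run enumeration: all substrings that start and end with
# the target base, length >= min_run, <= max_mismatch other bases; report the
# 3'-most (largest end), tie-broken by length.
oracle_polya <- function(seq, min_run, max_mismatch, target = "A") {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  w <- min(50L, n)
  lo <- n - w + 1L
  best <- NULL
  for (i in lo:n) {
    for (j in i:n) {
      if (ch[i] != target || ch[j] != target) next
      len <- j - i + 1L
      if (len < min_run) next
      if (sum(ch[i:j] != target) > max_mismatch) next
      if (is.null(best) || j > best$end ||
          (j == best$end && len > best$len)) {
        best <- list(start = i, end = j, len = len)
      }
    }
  }
  best
}

# Brute-force optimal partial matching (max cardinality, then min total
# distance) between two small spot lists under a distance cap.
oracle_match <- function(x, y, max_dist) {
  nx <- nrow(x); ny <- nrow(y)
  d <- sqrt(outer(x$row, y$row, "-")^2 + outer(x$col, y$col, "-")^2)
  best <- list(card = -1L, tot = Inf)
  used <- rep(FALSE, ny)
  rec <- function(i, card, tot) {
    if (i > nx) {
      if (card > best$card || (card == best$card && tot < best$tot)) {
        best <<- list(card = card, tot = tot)
      }
      return(invisible())
    }
    rec(i + 1L, card, tot)
    for (j in seq_len(ny)) {
      if (!used[j] && d[i, j] <= max_dist) {
        used[j] <<- TRUE
        rec(i + 1L, card + 1L, tot + d[i, j])
        used[j] <<- FALSE
      }
    }
  }
  if (nx > 0 && ny > 0) rec(1L, 0L, 0) else best <- list(card = 0L, tot = 0)
  best
}

# Random DNA without N, for oracle comparisons that rely on adist.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate k random positions of a sequence to a different base.
mutate_bases <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
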