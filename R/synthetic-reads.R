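#' TSS weight profile
#'
#' A per-transcript distribution of transcription start sites: probability
#' mass over genomic positions (0-based) on one chromosome and strand, plus
#' the transcript's genomic 3' end so the read simulator can build a body
#' from any sampled start to the end of the transcript.
#'
#' @param transcript_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param weights named numeric vector; names are 0-based genomic positions,
#'   values sum to 1 (tolerance 1e-9).
#' @param tx_end 0-based genomic position of the transcript's 3'-most base.
#'   Must be downstream of every weighted position (greater for `+`, smaller
#'   for `-`).
#' @return object of class `tss_profile`.
#' @export
tss_profile <- function(transcript_id, chrom, strand, weights, tx_end) {
  stopifnot(length(weights) > 0, !is.null(names(weights)))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("profile weights must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(weights < 0)) stop("profile weights must be non-negative", call. = FALSE)
  strand <- match.arg(strand, c("+", "-"))
  pos <- as.integer(names(weights))
  if (any(is.na(pos)) || any(pos < 0)) {
    stop("weight names must be non-negative 0-based positions", call. = FALSE)
  }
  stopifnot_scalar_number(tx_end, "tx_end", lower = 0)
  if (strand == "+" && any(pos > tx_end)) {
    stop("tx_end must be >= all weighted positions on '+'", call. = FALSE)
  }
  if (strand == "-" && any(pos < tx_end)) {
    stop("tx_end must be <= all weighted positions on '-'", call. = FALSE)
  }
  structure(
    list(transcript_id = as.character(transcript_id), chrom = as.character(chrom),
         strand = strand, weights = weights, tx_end = as.integer(tx_end)),
    class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("<tss_profile> %s %s:%s strand %s, %d position(s), tx_end %d\n",
              x$transcript_id, x$chrom,
              paste(range(as.integer(names(x$weights))), collapse = "-"),
              x$strand, length(x$weights), x$tx_end))
  invisible(x)
}

#' Read simulator configuration
#'
#' Parameters of the full-length cDNA read generator. A read is built as
#' `TSO + sense body (sampled TSS .. transcript 3' end) + polyA +
#' revcomp(rt_primer)`; contamination processes then truncate the 5' end
#' (reverse-transcription drop-off), reverse-complement the whole read
#' (antisense), or omit the TSO (adapterless).
#'
#' @param n_reads number of reads to draw.
#' @param truncation_fraction fraction of reads whose 5' end is shifted 3'.
#' @param truncation_shift list describing the shift distribution; currently
#'   `list(dist = "geometric", p = 0.02)`: shift = 1 + rgeom(p), truncated at
#'   the body length (longer shifts drop the read).
#' @param antisense_fraction fraction emitted as reverse complements.
#' @param adapterless_fraction fraction emitted without the TSO.
#' @param polya_length simulated polyA tail length (nt).
#' @param tso_sequence template-switching oligo appended at the 5' end.
#' @param rt_primer RT primer whose reverse complement ends the read.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads,
                            truncation_fraction = 0,
                            truncation_shift = list(dist = "geometric", p = 0.02),
                            antisense_fraction = 0,
                            adapterless_fraction = 0,
                            polya_length = 30L,
                            tso_sequence = "CAATGAAGTCGCAGGGTTGGG",
                            rt_primer = "AAGCAGTGGTATCAACGCAGAGTAC",
                            seed = NULL) {
  stopifnot_scalar_number(n_reads, "n_reads", lower = 1)
  stopifnot_scalar_number(truncation_fraction, "truncation_fraction", 0, 1)
  stopifnot_scalar_number(antisense_fraction, "antisense_fraction", 0, 1)
  stopifnot_scalar_number(adapterless_fraction, "adapterless_fraction", 0, 1)
  stopifnot_scalar_number(polya_length, "polya_length", lower = 0)
  check_dna(tso_sequence, "tso_sequence")
  check_dna(rt_primer, "rt_primer")
  if (!identical(truncation_shift$dist, "geometric")) {
    stop("only the geometric truncation shift is implemented", call. = FALSE)
  }
  structure(
    list(n_reads = as.integer(n_reads),
         truncation_fraction = truncation_fraction,
         truncation_shift = truncation_shift,
         antisense_fraction = antisense_fraction,
         adapterless_fraction = adapterless_fraction,
         polya_length = as.integer(polya_length),
         tso_sequence = tso_sequence, rt_primer = rt_primer, seed = seed),
    class = "read_sim_config")
}

#' Simulate full-length long cDNA reads with a truth table
#'
#' Draws reads from a set of TSS profiles over a genome, applying the
#' configured truncation / antisense / adapterless contamination processes.
#' Every stochastic choice is recorded in the truth table so downstream
#' stages can be checked against planted parameters. Reads whose sampled
#' truncation shift reaches or exceeds the body length are dropped and
#' logged (`dropped = TRUE`, no emitted read).
#'
#' @param profiles a `tss_profile` or list of them.
#' @param genome named character vector of chromosome sequences.
#' @param cfg a [read_sim_config()].
#' @param expression optional positive weights (one per profile) giving the
#'   relative abundance of each transcript; default uniform.
#' @return list with `reads` (data.frame `id`, `sequence`) and `truth`
#'   (data.frame with one row per drawn read: `read_id`, `transcript_id`,
#'   `chrom`, `strand`, `true_tss`, `five_prime` emitted genomic 5' end,
#'   `truncated`, `shift`, `antisense`, `adapterless`, `dropped`).
#' @export
simulate_reads <- function(profiles, genome, cfg, expression = NULL) {
  if (inherits(profiles, "tss_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("empty profile list", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "tss_profile")))
  for (p in profiles) {
    if (!p$chrom %in% names(genome)) {
      stop(sprintf("profile %s: chromosome %s not in genome", p$transcript_id,
                   p$chrom), call. = FALSE)
    }
    len <- nchar(genome[[p$chrom]])
    if (max(as.integer(names(p$weights)), p$tx_end) >= len) {
      stop(sprintf("profile %s: positions exceed chromosome length",
                   p$transcript_id), call. = FALSE)
    }
  }
  if (is.null(expression)) expression <- rep(1, length(profiles))
  stopifnot(length(expression) == length(profiles), all(expression > 0))

  with_seed(cfg$seed, {
    n <- cfg$n_reads
    which_tx <- sample.int(length(profiles), n, replace = TRUE,
                           prob = expression / sum(expression))
    true_tss <- integer(n)
    for (k in unique(which_tx)) {
      idx <- which(which_tx == k)
      w <- profiles[[k]]$weights
      pos <- as.integer(names(w))
      true_tss[idx] <- if (length(pos) == 1L) pos else {
        sample(pos, length(idx), replace = TRUE, prob = w)
      }
    }
    truncated <- runif(n) < cfg$truncation_fraction
    shift <- integer(n)
    shift[truncated] <- 1L + rgeom(sum(truncated), cfg$truncation_shift$p)
    antisense <- runif(n) < cfg$antisense_fraction
    adapterless <- runif(n) < cfg$adapterless_fraction

    chrom <- vapply(profiles, `[[`, character(1), "chrom")[which_tx]
    strand <- vapply(profiles, `[[`, character(1), "strand")[which_tx]
    tx_end <- vapply(profiles, `[[`, integer(1), "tx_end")[which_tx]

    five_prime <- ifelse(strand == "+", true_tss + shift, true_tss - shift)
    body_len <- ifelse(strand == "+", tx_end - five_prime + 1L,
                       five_prime - tx_end + 1L)
    dropped <- body_len < 1L
    five_prime[dropped] <- NA_integer_

    id <- sprintf("read_%06d", seq_len(n))
    truth <- data.frame(
      read_id = id, transcript_id = vapply(profiles, `[[`, character(1),
                                           "transcript_id")[which_tx],
      chrom = chrom, strand = strand, true_tss = true_tss,
      five_prime = five_prime, truncated = truncated, shift = shift,
      antisense = antisense, adapterless = adapterless, dropped = dropped,
      stringsAsFactors = FALSE)

    keep <- !dropped
    body <- character(sum(keep))
    ki <- which(keep)
    plus <- strand[ki] == "+"
    if (any(plus)) {
      i <- ki[plus]
      body[plus] <- mapply(function(ch, s, e) substr(genome[[ch]], s, e),
                           chrom[i], five_prime[i] + 1L, tx_end[i] + 1L,
                           USE.NAMES = FALSE)
    }
    if (any(!plus)) {
      i <- ki[!plus]
      body[!plus] <- revcomp(mapply(function(ch, s, e) substr(genome[[ch]], s, e),
                                    chrom[i], tx_end[i] + 1L, five_prime[i] + 1L,
                                    USE.NAMES = FALSE))
    }
    tail_a <- strrep("A", cfg$polya_length)
    rtp <- revcomp(cfg$rt_primer)
    seqs <- paste0(ifelse(adapterless[ki], "", cfg$tso_sequence),
                   body, tail_a, rtp)
    flip <- antisense[ki]
    seqs[flip] <- revcomp(seqs[flip])
    list(reads = data.frame(id = id[ki], sequence = seqs,
                            stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate a CAGE-style 5'-end track
#'
#' Multinomial sample of `n` 5'-end counts over one or more TSS profiles,
#' returned as a raw-scale [five_prime_track()] with `library_size = n`.
#'
#' @param profiles a `tss_profile` or list of them.
#' @param n total number of 5' ends to draw (scalar), or a vector with one
#'   count per profile.
#' @param seed integer seed.
#' @param expression optional per-profile relative abundances used to split a
#'   scalar `n` across profiles (multinomial); default uniform.
#' @return a raw `five_prime_track`.
#' @export
simulate_cage_track <- function(profiles, n, seed = NULL, expression = NULL) {
  if (inherits(profiles, "tss_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0, all(n >= 0), sum(n) > 0)
  with_seed(seed, {
    if (length(n) == 1L && length(profiles) > 1L) {
      if (is.null(expression)) expression <- rep(1, length(profiles))
      n <- as.integer(rmultinom(1, n, expression / sum(expression)))
    } else if (length(n) == 1L) {
      n <- as.integer(n)
    }
    stopifnot(length(n) == length(profiles))
    pieces <- lapply(seq_along(profiles), function(k) {
      p <- profiles[[k]]
      if (n[k] == 0L) return(NULL)
      w <- p$weights
      cnt <- as.integer(rmultinom(1, n[k], w))
      keep <- cnt > 0L
      data.frame(chrom = p$chrom, strand = p$strand,
                 pos = as.integer(names(w))[keep], count = cnt[keep],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
    five_prime_track(df, library_size = sum(n), scale = "raw")
  })
}

#' Sharp synthetic TSS profiles along one chromosome
#'
#' Builds the stated synthetic world used by the concordance analyses:
#' `n` transcripts laid out every 3000 nt on one chromosome, alternating
#' strands, each with a sharp dominant start (weight `dominant_weight`) and
#' `n_minor` satellite starts within 12 nt whose weights decay geometrically.
#' Per-transcript expression is log-uniform over two decades, emulating the
#' expression range across which concordance is binned.
#'
#' @param n number of transcripts.
#' @param dominant_weight probability mass at the dominant start.
#' @param n_minor number of satellite start positions.
#' @param body_length transcript body length (nt).
#' @param seed integer seed.
#' @return list with `profiles` (list of [tss_profile()]), `expression`
#'   (relative abundances), `chrom` and `chrom_length`.
#' @export
simulate_tss_profiles <- function(n, dominant_weight = 0.75, n_minor = 4L,
                                  body_length = 1500L, seed = NULL) {
  stopifnot(n >= 1, dominant_weight > 0, dominant_weight <= 1, n_minor >= 0)
  chrom <- "chrS"
  spacing <- 3000L
  chrom_length <- as.integer(n * spacing + 2000L)
  with_seed(seed, {
    profiles <- vector("list", n)
    for (k in seq_len(n)) {
      slot <- (k - 1L) * spacing
      strand <- if (k %% 2L == 1L) "+" else "-"
      tss <- if (strand == "+") slot + 1000L else slot + 2500L
      offs <- sample(setdiff(-12:12, 0), n_minor)
      w_min <- 0.5 ^ seq_len(n_minor)
      w <- c(dominant_weight, (1 - dominant_weight) * w_min / sum(w_min))
      pos <- c(tss, tss + offs)
      o <- order(pos)
      weights <- setNames(w[o], pos[o])
      tx_end <- if (strand == "+") tss + body_length - 1L else tss - body_length + 1L
      profiles[[k]] <- tss_profile(sprintf("tx%03d", k), chrom, strand,
                                   weights, tx_end)
    }
    expression <- 10 ^ runif(n, 0, 2)
    list(profiles = profiles, expression = expression, chrom = chrom,
         chrom_length = chrom_length)
  })
}

#' Alignments implied by a read-simulation truth table
#'
#' Converts the truth table of [simulate_reads()] into a single-block
#' [alignment_set()] (one exon from the emitted 5' end to the transcript 3'
#' end, on the sense strand). This bypasses the external spliced aligner,
#' whose job is out of scope, while preserving the genomic 5' ends the
#' downstream track builder consumes.
#'
#' @param truth truth table from [simulate_reads()].
#' @param profiles the profile list the reads were simulated from.
#' @return an `alignment_set` of the non-dropped reads.
#' @export
alignments_from_truth <- function(truth, profiles) {
  if (inherits(profiles, "tss_profile")) profiles <- list(profiles)
  ends <- setNames(vapply(profiles, `[[`, integer(1), "tx_end"),
                   vapply(profiles, `[[`, character(1), "transcript_id"))
  t2 <- truth[!truth$dropped, , drop = FALSE]
  tx_end <- ends[t2$transcript_id]
  start <- ifelse(t2$strand == "+", t2$five_prime, tx_end)
  end <- ifelse(t2$strand == "+", tx_end + 1L, t2$five_prime + 1L)
  blocks <- mapply(function(s, e) cbind(start = s, end = e), start, end,
                   SIMPLIFY = FALSE)
  alignment_set(read_id = t2$read_id, chrom = t2$chrom, strand = t2$strand,
                blocks = blocks)
}

#' Write reads to FASTQ
#'
#' Phred-33 FASTQ with a constant quality character, via Biostrings.
#'
#' @param reads data.frame with `id` and `sequence` (as produced by
#'   [simulate_reads()]).
#' @param path output file path.
#' @param quality_char constant per-base quality character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTA/FASTQ file into a reads data.frame
#'
#' @param path input path (`.fa`, `.fq`, optionally gzipped).
#' @param format `"fastq"` or `"fasta"`; guessed from the extension when
#'   missing.
#' @return data.frame with `id` and `sequence`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path)) "fasta" else "fastq"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(id = sub(" .*", "", names(x)),
             sequence = unname(as.character(x)), stringsAsFactors = FALSE)
}
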