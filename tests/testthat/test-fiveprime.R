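test_that("five_prime_ends places counts at the 5'-most genomic base", {
  aln <- alignment_set(
    read_id = c("r1", "r2", "r3"),
    chrom = rep("chr1", 3), strand = c("+", "-", "+"),
    blocks = list(cbind(start = 100L, end = 200L),
                  cbind(start = 100L, end = 200L),
                  cbind(start = c(100L, 300L), end = c(150L, 400L))))
  trk <- five_prime_ends(aln)
  expect_equal(trk$library_size, 3L)
  expect_equal(sum(trk$counts$count), 3)
  plus <- trk$counts[trk$counts$strand == "+", ]
  minus <- trk$counts[trk$counts$strand == "-", ]
  expect_equal(plus$pos, 100)          # spliced read counts at pre-splice 5' end
  expect_equal(plus$count, 2)
  expect_equal(minus$pos, 199)         # last base of the last block on '-'
})

test_that("tracks are order-independent and conserve counts", {
  set.seed(5)
  n <- 500
  starts <- sample.int(10000, n, replace = TRUE)
  aln <- alignment_set(
    read_id = sprintf("r%d", seq_len(n)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    blocks = lapply(starts, function(s) cbind(start = s, end = s + 100L)))
  t1 <- five_prime_ends(aln)
  perm <- sample.int(n)
  aln2 <- alignment_set(aln$read_id[perm], aln$chrom[perm], aln$strand[perm],
                        aln$blocks[perm])
  expect_identical(t1$counts, five_prime_ends(aln2)$counts)
  expect_equal(sum(t1$counts$count), n)

  # coordinate-mirror property: flipping the genome flips positions/strands
  L <- 20000L
  mirror <- alignment_set(
    aln$read_id, aln$chrom,
    ifelse(aln$strand == "+", "-", "+"),
    lapply(aln$blocks, function(b) {
      cbind(start = L - b[, "end"], end = L - b[, "start"])
    }))
  tm <- five_prime_ends(mirror)
  got <- tm$counts[order(tm$counts$chrom, tm$counts$strand, tm$counts$pos), ]
  want <- t1$counts
  want$pos <- L - 1L - want$pos
  want$strand <- ifelse(want$strand == "+", "-", "+")
  want <- want[order(want$chrom, want$strand, want$pos), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("secondary alignments are excluded by default", {
  aln <- alignment_set(c("r1", "r1"), c("chr1", "chr1"), c("+", "+"),
                       list(cbind(start = 10L, end = 20L),
                            cbind(start = 50L, end = 60L)),
                       is_primary = c(TRUE, FALSE))
  expect_equal(five_prime_ends(aln)$library_size, 1L)
  expect_equal(five_prime_ends(aln, primary_only = FALSE)$library_size, 2L)
})

test_that("to_rpm rescales exactly once", {
  trk <- five_prime_track(
    data.frame(chrom = "chr1", strand = "+", pos = c(5L, 9L),
               count = c(3, 7)), library_size = 10L)
  r <- to_rpm(trk)
  expect_equal(r$counts$count, c(3e5, 7e5))
  expect_equal(sum(r$counts$count), 1e6)
  expect_error(to_rpm(r), "already RPM")
  one <- five_prime_track(data.frame(chrom = "c", strand = "+", pos = 1L,
                                     count = 1), library_size = 1L)
  expect_equal(to_rpm(one)$counts$count, 1e6)
})

test_that("BAM round trip preserves blocks, strand and primary flags", {
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 60, "50M100N50M", "*", 0, 0, "*", "*",
          sep = "\t"),
    paste("r2", 16, "chr1", 101, 60, "100M", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r3", 256, "chr1", 201, 0, "50M", "*", 0, 0, "*", "*", sep = "\t"))
  samfile <- tempfile(fileext = ".sam")
  writeLines(sam, samfile)
  bam <- Rsamtools::asBam(samfile, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  aln <- read_alignments(bam)
  expect_equal(nrow(aln), 2)          # secondary dropped
  expect_equal(aln$strand, c("+", "-"))
  expect_equal(aln$blocks[[1]],
               cbind(start = c(100L, 250L), end = c(150L, 300L)))
  trk <- five_prime_ends(aln)
  expect_equal(trk$counts$pos[trk$counts$strand == "+"], 100)
  expect_equal(trk$counts$pos[trk$counts$strand == "-"], 199)
})

test_that("bedGraph round trip preserves a track", {
  trk <- five_prime_track(
    data.frame(chrom = c("chr1", "chr1", "chr2"), strand = c("+", "-", "+"),
               pos = c(10L, 99L, 5L), count = c(2, 3, 1)),
    library_size = 6L)
  prefix <- tempfile()
  write_track_bedgraph(trk, prefix)
  back <- read_track_bedgraph(prefix)
  expect_equal(back$counts, trk$counts)
  expect_equal(back$library_size, trk$library_size)
  expect_equal(back$scale, "raw")
})

test_that("assign_to_models recovers planted isoform proportions exactly", {
  models <- planted_isoform_models()
  reads <- planted_isoform_reads()
  res <- assign_to_models(reads, models, junction_tolerance = 0)
  expect_equal(res$n_assigned, 104L)
  expect_equal(res$n_unassigned, 0L)
  expect_equal(res$counts$count, c(60, 37, 6, 1, 0))
  expect_equal(res$counts$percent, 100 * c(60, 37, 6, 1, 0) / 104)
})

test_that("assign_to_models applies the compatibility rules", {
  models <- planted_isoform_models()
  mk <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  }
  aln <- alignment_set(
    read_id = c("exact", "novel_intron", "mono_e", "mono_intronic",
                "jitter", "wrong_strand"),
    chrom = rep("chrA", 6),
    strand = c("+", "+", "+", "+", "+", "-"),
    blocks = list(
      mk(210, 300, 400, 500, 600, 690),  # iso_a chain
      mk(210, 300, 520, 690),            # intron (300,520) matches nothing
      mk(660, 880),                      # inside mono-exonic iso_e
      mk(250, 450),                      # overlaps iso_a/d introns
      mk(210, 302, 400, 500, 600, 690),  # donor off by 2
      mk(210, 300, 400, 500, 600, 690)))
  res0 <- assign_to_models(aln, models, junction_tolerance = 0)
  lab <- vapply(res0$assignments, function(x) paste(x, collapse = ","), "")
  expect_equal(lab, c("iso_a", "", "iso_e", "", "", ""))
  expect_equal(res0$n_unassigned, 4L)
  res5 <- assign_to_models(aln, models, junction_tolerance = 5)
  expect_true("iso_a" %in% res5$assignments[[5]])
})

test_that("ambiguous reads are split fractionally and totals are conserved", {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  }
  models <- list(
    transcript_model("short", "g", "chr1", "+", ex(0, 100, 200, 300)),
    transcript_model("long", "g", "chr1", "+", ex(0, 100, 200, 400)))
  aln <- alignment_set("r1", "chr1", "+",
                       list(ex(10, 100, 200, 290)))
  res <- assign_to_models(aln, models)
  expect_equal(res$counts$count, c(0.5, 0.5))
  expect_equal(sum(res$counts$count), res$n_assigned, tolerance = 1e-9)
})
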