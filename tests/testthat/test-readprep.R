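spec <- adapter_spec()
tso <- spec$tso_sequence
tso_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tso)))

test_that("locate_tso finds exact and antisense adapters", {
  set.seed(1)
  body <- random_dna(100)
  hit <- locate_tso(paste0(tso, body), spec)
  expect_equal(hit$orientation, "sense")
  expect_equal(hit$edit_distance, 0L)
  expect_equal(c(hit$start, hit$end), c(0L, nchar(tso)))

  hit2 <- locate_tso(paste0(body, tso_rc), spec)
  expect_equal(hit2$orientation, "antisense")
  expect_equal(hit2$edit_distance, 0L)
  expect_equal(c(hit2$start, hit2$end), c(100L, 100L + nchar(tso)))
})

test_that("locate_tso respects the error budget (2 in, 3 out at 10%)", {
  set.seed(2)
  for (rep in 1:10) {
    body <- random_dna(179)
    read2 <- paste0(mutate_bases(tso, 2), body)
    read3 <- paste0(mutate_bases(tso, 3), body)
    h2 <- locate_tso(read2, spec)
    expect_equal(h2$orientation, "sense")
    expect_lte(h2$edit_distance, 2L)
    h3 <- locate_tso(read3, spec)
    # 3 substitutions exceed floor(0.1*21)=2 for the full adapter; a shorter
    # suffix match can still pass only if the mutations cluster in the
    # discarded prefix, which mutate_bases makes possible but rare; verify
    # against the exhaustive oracle instead of asserting blindly.
    o3 <- oracle_locate_tso(read3, spec)
    expect_equal(h3$orientation, o3$orientation)
  }
})

test_that("N bases never match in adapter or polyA scans", {
  read <- paste0(sub("^...", "NNN", tso), random_dna(80))
  h <- locate_tso(read, spec)
  # 3 N mismatches in the full adapter exceed the budget; the 18-nt suffix
  # anchored at position 3 cannot apply (it must sit at the read start), but
  # shorter clean suffixes can still match at the start after edits; verify
  # the edit distance honours N-as-mismatch by checking a clean interior case
  expect_true(h$orientation != "sense" || h$edit_distance > 0)
  expect_null(detect_polya(paste0("ACG", "AAAANNAAAA"), spec))
})

test_that("detect_polya follows the run definition", {
  expect_equal(detect_polya(paste0("ACGT", strrep("A", 12)), spec)$start, 5L)
  expect_null(detect_polya(paste0(strrep("A", 5), "CGCGCG"), spec))
  hit <- detect_polya("ACGAAAAGAAAA", spec)
  expect_equal(hit$start, 4L)
  expect_equal(hit$length, 9L)
  # symmetric 5' polyT search (body free of T so the run cannot extend)
  hit5 <- detect_polya(paste0(strrep("T", 10), strrep("GAC", 20)), spec,
                       end = "5T")
  expect_equal(c(hit5$start, hit5$end), c(1L, 10L))
})

test_that("detect_polya agrees with exhaustive run enumeration", {
  set.seed(3)
  for (i in 1:200) {
    # A-rich tails make qualifying runs common
    seq <- paste0(random_dna(30),
                  paste(sample(c("A", "A", "A", "C", "G", "T"), 40,
                               replace = TRUE), collapse = ""))
    got <- detect_polya(seq, spec)
    want <- oracle_polya(seq, spec$polya_min_run, spec$polya_max_mismatches)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("select_full_length keeps, orients and reports correctly", {
  set.seed(4)
  body <- random_dna(120)
  full <- paste0(tso, body, strrep("A", 12))
  reads <- data.frame(
    id = c("sense", "anti", "naked"),
    sequence = c(full,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(full))),
                 body),
    stringsAsFactors = FALSE)
  res <- select_full_length(reads, spec)
  expect_equal(res$report$n_input, 3)
  expect_equal(res$report$n_kept, 2)
  expect_equal(res$report$n_discarded_no_tso, 1)
  expect_equal(res$report$n_reverse_complemented, 1)
  expect_equal(res$report$n_polya_detected, 2)
  expect_identical(res$reads$sense_sequence[1], res$reads$sense_sequence[2])
  expect_equal(res$reads$was_reverse_complemented, c(FALSE, TRUE))

  empty <- select_full_length(reads[0, ], spec)
  expect_equal(empty$report$n_input, 0)
  expect_equal(empty$report$n_kept, 0)
})

test_that("select_full_length recovers simulated orientation truth", {
  world <- small_world(10, seed = 71)
  cfg <- read_sim_config(n_reads = 600, antisense_fraction = 0.3,
                         adapterless_fraction = 0.2, seed = 72)
  sim <- simulate_reads(world$profiles, world$genome, cfg,
                        expression = world$expression)
  res <- select_full_length(sim$reads, spec)
  truth <- sim$truth[match(res$reads$id, sim$truth$read_id), ]
  expect_false(any(truth$adapterless))
  expect_gte(mean(res$reads$was_reverse_complemented == truth$antisense), 0.99)
  # report conservation (chimeras counted separately)
  expect_equal(res$report$n_input,
               res$report$n_kept + res$report$n_discarded_no_tso +
                 res$report$n_chimeric)
})

test_that("orientation is idempotent and reverse-complement symmetric", {
  world <- small_world(5, seed = 81)
  cfg <- read_sim_config(n_reads = 60, antisense_fraction = 0.5, seed = 82)
  sim <- simulate_reads(world$profiles, world$genome, cfg,
                        expression = world$expression)
  res <- select_full_length(sim$reads, spec)
  # idempotence: re-prepending the TSO and rerunning reproduces sense_sequence
  again <- select_full_length(
    data.frame(id = res$reads$id,
               sequence = paste0(tso, res$reads$sense_sequence),
               stringsAsFactors = FALSE), spec)
  expect_identical(again$reads$sense_sequence, res$reads$sense_sequence)
  expect_false(any(again$reads$was_reverse_complemented))
  # symmetry: a read and its reverse complement give the same sense sequence
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$reads$sequence)))
  res_rc <- select_full_length(
    data.frame(id = sim$reads$id, sequence = rc, stringsAsFactors = FALSE),
    spec)
  expect_identical(res_rc$reads$sense_sequence, res$reads$sense_sequence)
  expect_identical(res_rc$reads$was_reverse_complemented,
                   !res$reads$was_reverse_complemented)
})
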