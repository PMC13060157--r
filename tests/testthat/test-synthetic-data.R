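test_that("simulate_reads honours degenerate configurations", {
  genome <- c(chr1 = strrep("ACGT", 200))
  prof <- tss_profile("t1", "chr1", "+", c(`100` = 1), tx_end = 400L)
  cfg <- read_sim_config(n_reads = 50, seed = 7)
  sim <- simulate_reads(prof, genome, cfg)
  expect_equal(nrow(sim$reads), 50)
  expect_true(all(startsWith(sim$reads$sequence, cfg$tso_sequence)))
  expect_true(all(sim$truth$five_prime == 100))
  expect_true(all(sim$truth$true_tss == 100))

  cfg2 <- read_sim_config(n_reads = 30, adapterless_fraction = 1, seed = 8)
  sim2 <- simulate_reads(prof, genome, cfg2)
  expect_false(any(startsWith(sim2$reads$sequence, cfg2$tso_sequence)))
  expect_true(all(sim2$truth$adapterless))

  expect_error(simulate_reads(list(), genome, cfg), "empty profile")
})

test_that("simulate_reads 5'-position frequencies follow the profile weights", {
  # binomial oracle: observed frequency of the 0.7-weight start within 3 SE
  genome <- c(chr1 = strrep("ACGT", 300))
  prof <- tss_profile("t1", "chr1", "+", c(`100` = 0.7, `150` = 0.3),
                      tx_end = 900L)
  cfg <- read_sim_config(n_reads = 10000, seed = 42)
  sim <- simulate_reads(prof, genome, cfg)
  p_hat <- mean(sim$truth$true_tss == 100)
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(p_hat - 0.7), 3 * se)
})

test_that("simulate_reads truth tables replay to the emitted reads", {
  world <- small_world(6, seed = 21)
  cfg <- read_sim_config(n_reads = 300, truncation_fraction = 0.3,
                         antisense_fraction = 0.3, adapterless_fraction = 0.2,
                         seed = 22)
  sim <- simulate_reads(world$profiles, world$genome, cfg,
                        expression = world$expression)
  ends <- setNames(vapply(world$profiles, `[[`, integer(1), "tx_end"),
                   vapply(world$profiles, `[[`, character(1), "transcript_id"))
  emitted <- setNames(sim$reads$sequence, sim$reads$id)
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    if (row$dropped) {
      expect_false(row$read_id %in% names(emitted))
      next
    }
    txe <- ends[[row$transcript_id]]
    body <- if (row$strand == "+") {
      substr(world$genome[[row$chrom]], row$five_prime + 1, txe + 1)
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(world$genome[[row$chrom]], txe + 1, row$five_prime + 1))))
    }
    read <- paste0(if (row$adapterless) "" else cfg$tso_sequence, body,
                   strrep("A", cfg$polya_length),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(cfg$rt_primer))))
    if (row$antisense) {
      read <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    }
    expect_identical(unname(emitted[[row$read_id]]), read)
  }
})

test_that("generators are seed-deterministic", {
  world <- small_world(4, seed = 31)
  cfg <- read_sim_config(n_reads = 100, truncation_fraction = 0.2,
                         antisense_fraction = 0.2, seed = 32)
  s1 <- simulate_reads(world$profiles, world$genome, cfg)
  s2 <- simulate_reads(world$profiles, world$genome, cfg)
  expect_identical(s1, s2)

  t1 <- simulate_cage_track(world$profiles, 5000, seed = 33)
  t2 <- simulate_cage_track(world$profiles, 5000, seed = 33)
  expect_identical(t1, t2)

  icfg <- image_sim_config(n_spots_per_channel = c(red = 30L, green = 20L),
                           seed = 34)
  expect_identical(simulate_image(icfg), simulate_image(icfg))

  ccfg <- ct_sim_config(c(top = 4, mid = 2, bot = 1), replicate_noise_sd = 0.3,
                        n_replicates = 3, seed = 35)
  expect_identical(simulate_ct(ccfg), simulate_ct(ccfg))
})

test_that("simulate_cage_track conserves counts and matches the binomial oracle", {
  prof <- tss_profile("t1", "chr1", "+", c(`10` = 1), tx_end = 50L)
  trk <- simulate_cage_track(prof, 5, seed = 41)
  expect_equal(nrow(trk$counts), 1)
  expect_equal(trk$counts$count, 5)
  expect_equal(trk$counts$pos, 10)

  prof2 <- tss_profile("t2", "chr1", "+", c(`10` = 0.5, `20` = 0.5),
                       tx_end = 50L)
  trk2 <- simulate_cage_track(prof2, 100000, seed = 42)
  expect_equal(sum(trk2$counts$count), 100000)
  se <- sqrt(100000 * 0.25)
  expect_lt(abs(trk2$counts$count[1] - 50000), 3 * se)

  world <- small_world(5, seed = 43)
  trk3 <- simulate_cage_track(world$profiles, 20000, seed = 44,
                              expression = world$expression)
  expect_equal(sum(trk3$counts$count), 20000)
  expect_equal(trk3$library_size, 20000L)
})

test_that("simulate_image plants spots where it says it does", {
  cfg0 <- image_sim_config(n_spots_per_channel = c(red = 0L, green = 0L),
                           seed = 51)
  img0 <- simulate_image(cfg0)
  expect_equal(nrow(img0$truth_spots), 0)

  cfg1 <- image_sim_config(n_spots_per_channel = c(red = 40L),
                           nuclear_spot_fraction = 1, seed = 52)
  img1 <- simulate_image(cfg1)
  tt <- img1$truth_spots
  expect_true(all(img1$truth_mask[cbind(round(tt$row), round(tt$col))]))

  # impossible geometry: too many spots for the separation constraint
  tiny <- data.frame(row = 40, col = 40, radius = 8)
  cfg_bad <- image_sim_config(height = 64, width = 64, nucleus_geometry = tiny,
                              n_spots_per_channel = c(red = 500L),
                              nuclear_spot_fraction = 1, seed = 53)
  expect_error(simulate_image(cfg_bad), "retries exhausted")
})

test_that("simulate_ct matches its closed form and guards its range", {
  cfg <- ct_sim_config(c(f1 = 8, f2 = 4, f3 = 1), ct_at_unit_abundance = 30,
                       replicate_noise_sd = 0, seed = 61)
  tab <- simulate_ct(cfg)
  expect_equal(tab$ct, c(27, 28, 30))

  cfg_eq <- ct_sim_config(c(f1 = 2, f2 = 2, f3 = 2), replicate_noise_sd = 0)
  expect_equal(length(unique(simulate_ct(cfg_eq)$ct)), 1)

  cfg_bad <- ct_sim_config(c(f1 = 2^50, f2 = 1), ct_at_unit_abundance = 30,
                           replicate_noise_sd = 0)
  expect_error(simulate_ct(cfg_bad), "outside")
})
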