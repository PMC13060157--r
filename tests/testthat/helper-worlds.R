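# Shared fixture builders (all generated in code; no stored data files).

# Five transcript models with mutually incompatible intron chains plus one
# mono-exonic model, emulating a locus where five isoforms share exons but
# differ by alternative introns. Coordinates are 0-based half-open.
planted_isoform_models <- function() {
  ex <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  }
  list(
    a = transcript_model("iso_a", "locus", "chrA", "+",
                         ex(200, 300, 400, 500, 600, 700)),
    b = transcript_model("iso_b", "locus", "chrA", "+",
                         ex(200, 300, 430, 500, 600, 700)),
    c = transcript_model("iso_c", "locus", "chrA", "+",
                         ex(320, 380, 420, 500, 600, 700)),
    d = transcript_model("iso_d", "locus", "chrA", "+",
                         ex(80, 140, 180, 300, 400, 500)),
    e = transcript_model("iso_e", "locus", "chrA", "+", ex(650, 900))
  )
}

# 104 spliced reads planted on the five models in fixed proportions
# 60 / 37 / 6 / 1 / 0.
planted_isoform_reads <- function() {
  blk <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  }
  proto <- list(
    a = blk(210, 300, 400, 500, 600, 690),
    b = blk(210, 300, 430, 500, 600, 690),
    c = blk(330, 380, 420, 500, 600, 690),
    d = blk(90, 140, 180, 300, 400, 480)
  )
  n <- c(a = 60L, b = 37L, c = 6L, d = 1L)
  blocks <- unlist(lapply(names(n), function(k) rep(list(proto[[k]]), n[k])),
                   recursive = FALSE)
  alignment_set(read_id = sprintf("r%03d", seq_len(sum(n))),
                chrom = rep("chrA", sum(n)), strand = rep("+", sum(n)),
                blocks = blocks)
}

# Small synthetic concordance world shared across tests.
small_world <- function(n = 20, seed = 11) {
  world <- simulate_tss_profiles(n, seed = seed)
  world$genome <- random_genome(setNames(world$chrom_length, world$chrom),
                                seed = seed + 1L)
  world$models <- models_from_profiles(world$profiles)
  world
}
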