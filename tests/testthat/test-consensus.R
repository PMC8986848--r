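# Family building, tag-neighbour merging and majority-vote collapsing

test_that("reads sharing a key form one family; position splits families", {
  r3 <- make_reads(bases = rep("ACGT", 3L), tag = "AAAAAAAAAA", start = 5L)
  fam <- build_families(r3)
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$size, 3L)

  r2 <- make_reads(bases = rep("ACGT", 2L), tag = "AAAAAAAAAA",
                   start = c(5L, 6L))
  expect_equal(nrow(build_families(r2)), 2L)

  # strand is part of the key
  rs <- make_reads(bases = rep("ACGT", 2L), tag = "AAAAAAAAAA",
                   start = 5L, strand = c("+", "-"))
  expect_equal(nrow(build_families(rs)), 2L)
})

test_that("families partition the input reads", {
  set.seed(21)
  reads <- make_reads(bases = random_dna_strings(200L, 12L),
                      tag = sample(random_tags(40L), 200L, replace = TRUE),
                      start = sample(0:5, 200L, replace = TRUE))
  fam <- build_families(reads)
  expect_equal(sum(fam$size), nrow(reads))
  expect_setequal(unlist(fam$members), seq_len(nrow(reads)))
})

test_that("directional merging absorbs a small tag neighbour", {
  reads <- make_reads(
    bases = rep("ACGT", 11L),
    tag = c(rep("AAAAAAAAAA", 10L), "AAAAAAAAAT"),
    start = 5L)
  reads$read_id <- paste0("r", 1:11)
  fam <- merge_tag_neighbors(build_families(reads), 1L)
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$size, 11L)
  expect_equal(fam$tag, "AAAAAAAAAA")
})

test_that("equal-sized tag neighbours are never merged", {
  reads <- make_reads(
    bases = rep("ACGT", 10L),
    tag = rep(c("AAAAAAAAAA", "AAAAAAAAAT"), each = 5L),
    start = 5L)
  fam <- merge_tag_neighbors(build_families(reads), 1L)
  expect_equal(nrow(fam), 2L)
  expect_equal(sort(fam$size), c(5L, 5L))
})

test_that("tag merging moves the family count toward the true molecule count", {
  ref <- tiny_reference(400L, seed = 31L)
  panel <- tibble(chrom = "chrT", start = 100L, end = 260L)
  cfg <- simulation_config(ref, panel, input_mass_ng = 3.8, recovery = 0.221,
                           raw_substitution_rate = 0, raw_indel_rate = 0,
                           tag_error_rate = 0.01)
  sim <- simulate_sample(cfg, seed = 55L)
  n_true <- nrow(sim$truth$molecules)
  fam <- build_families(sim$reads)
  merged <- merge_tag_neighbors(fam, 1L)
  expect_lt(abs(nrow(merged) - n_true), abs(nrow(fam) - n_true))
})

test_that("strict >70% vote: 8/10 wins, 7/10 yields N, size-1 is identity", {
  mk_family <- function(n_alt, n_total) {
    # alt reads carry G at offset 2 of an ACGT-repeat template
    template <- "ACTA"
    alt <- "AGTA"
    make_reads(bases = c(rep(alt, n_alt), rep(template, n_total - n_alt)),
               tag = "CCCCCCCCCC", start = 10L)
  }
  cfg <- consensus_config()
  r8 <- collapse_family(mk_family(8L, 10L), cfg)
  expect_equal(r8$bases, "AGTA")
  expect_equal(r8$family_size, 10L)

  r7 <- collapse_family(mk_family(7L, 10L), cfg)
  expect_equal(r7$bases, "ANTA")

  r1 <- collapse_family(mk_family(0L, 1L), cfg)
  expect_equal(r1$bases, "ACTA")
})

test_that("one additional supporting read tips the 70% boundary", {
  base <- make_reads(bases = c(rep("AGTA", 7L), rep("ACTA", 3L)),
                     tag = "CCCCCCCCCC", start = 10L)
  at_boundary <- collapse_family(base, consensus_config())
  expect_equal(substr(at_boundary$bases, 2L, 2L), "N")

  extra <- bind_rows(base, make_reads(bases = "AGTA", tag = "CCCCCCCCCC",
                                      start = 10L, read_id = "rx"))
  above <- collapse_family(extra, consensus_config())
  expect_equal(substr(above$bases, 2L, 2L), "G")   # 8/11 = 72.7% > 70%
})

test_that("undersized families are rejected, not erred", {
  fam <- make_reads(bases = "ACGT", tag = "CCCCCCCCCC")
  out <- collapse_family(fam, consensus_config(min_family_size = 2L))
  expect_true(out$rejected)
  expect_equal(out$reason, "family_too_small")
})

test_that("consensus matches a brute-force voter on random families", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:8, 1L)
    len <- sample(6:15, 1L)
    template <- random_dna_strings(1L, len)
    bases <- vapply(seq_len(n), function(i) {
      b <- template
      nmut <- rpois(1L, 1.2)
      for (j in seq_len(nmut)) {
        p <- sample.int(len, 1L)
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1L)
      }
      b
    }, "")
    fam <- make_reads(bases = bases, tag = "GGGGGGGGGG", start = 20L)
    got <- collapse_family(fam, consensus_config())
    want <- oracle_collapse(fam$bases, fam$start, fam$cigar)
    expect_identical(got$bases, want$bases)
    expect_identical(got$key$start, want$start)
  }
})

test_that("deletion-carrying families vote like the brute-force oracle", {
  set.seed(78)
  for (rep in 1:10) {
    n <- sample(3:6, 1L)
    template <- random_dna_strings(1L, 12L)
    with_del <- sample(c(TRUE, FALSE), n, replace = TRUE)
    bases <- ifelse(with_del,
                    paste0(substr(template, 1, 4), substr(template, 8, 12)),
                    template)
    cigar <- ifelse(with_del, "4M3D5M", "12M")
    fam <- make_reads(bases = bases, tag = "GGGGGGGGGG", start = 0L,
                      cigar = cigar)
    got <- collapse_family(fam, consensus_config())
    want <- oracle_collapse(fam$bases, fam$start, fam$cigar)
    expect_identical(got$bases, want$bases)
  }
})

test_that("collapse is invariant under read-order permutation", {
  ref <- tiny_reference(300L, seed = 41L)
  panel <- tibble(chrom = "chrT", start = 50L, end = 250L)
  cfg <- simulation_config(ref, panel, input_mass_ng = 2,
                           raw_substitution_rate = 1e-3)
  sim <- simulate_sample(cfg, seed = 99L)
  perm <- withr::with_seed(5L, sample.int(nrow(sim$reads)))
  a <- collapse_families(sim$reads)
  b <- collapse_families(sim$reads[perm, ])
  key <- function(x) arrange(as_tibble(x), chrom, start, strand, tag)
  expect_equal(key(a), key(b))
  pa <- build_pileup(a, panel, ref)
  pb <- build_pileup(b, panel, ref)
  expect_equal(as.data.frame(pa), as.data.frame(pb))
})

test_that("a reference-identical SSCS contributes one ref count everywhere", {
  ref <- tiny_reference(60L, seed = 51L)
  panel <- tibble(chrom = "chrT", start = 10L, end = 50L)
  reads <- make_reads(bases = substr(ref[[1]], 11L, 50L),
                      tag = "ACACACACAC", start = 10L)
  pile <- build_pileup(collapse_families(reads), panel, ref)
  tb <- as_tibble(pile)
  expect_true(all(tb$coverage == 1L))
  ref_count <- vapply(seq_len(nrow(tb)), function(i) {
    tb[[paste0(tb$ref[i], "_f")]][i] + tb[[paste0(tb$ref[i], "_r")]][i]
  }, 1L)
  expect_true(all(ref_count == 1L))
})

test_that("alt and coverage counts match a crafted 3-in-165 pileup", {
  ref <- tiny_reference(40L, seed = 61L)
  panel <- tibble(chrom = "chrT", start = 15L, end = 25L)
  pos <- 20L
  ref_base <- substr(ref[[1]], pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  set.seed(62)
  pile <- one_position_pileup(ref, panel, pos, alt, n_ref = 162L, n_alt = 3L)
  row <- as_tibble(pile) |> filter(pos == !!pos)
  expect_equal(row$coverage, 165L)
  expect_equal(row[[paste0(alt, "_f")]] + row[[paste0(alt, "_r")]], 3L)
})

test_that("pileup coverage never exceeds the number of consensus molecules", {
  ref <- tiny_reference(300L, seed = 71L)
  panel <- tibble(chrom = "chrT", start = 50L, end = 250L)
  for (s in c(1L, 2L, 3L)) {
    cfg <- simulation_config(ref, panel, input_mass_ng = 1.5,
                             raw_substitution_rate = 1e-3)
    sscs <- collapse_families(simulate_sample(cfg, seed = s)$reads)
    pile <- build_pileup(sscs, panel, ref)
    expect_true(all(pile$coverage <= nrow(sscs)))
    expect_equal(pile$coverage, pile$cov_f + pile$cov_r)
  }
})

test_that("N consensus bases contribute neither alleles nor coverage", {
  ref <- tiny_reference(40L, seed = 81L)
  panel <- tibble(chrom = "chrT", start = 0L, end = 40L)
  # family of 2 disagreeing at offset 2 -> N there
  template <- substr(ref[[1]], 11L, 18L)
  mutated <- template
  substr(mutated, 3L, 3L) <- setdiff(c("A", "C", "G", "T"),
                                     substr(template, 3L, 3L))[1]
  reads <- make_reads(bases = c(template, mutated), tag = "TTTTTTTTTT",
                      start = 10L)
  pile <- build_pileup(collapse_families(reads), panel, ref)
  tb <- as_tibble(pile)
  expect_equal(tb$coverage[tb$pos == 12L], 0L)
  expect_equal(tb$coverage[tb$pos == 11L], 1L)
})

test_that("consensus suppresses raw-read errors at realistic family sizes", {
  ref <- tiny_reference(400L, seed = 91L)
  panel <- tibble(chrom = "chrT", start = 100L, end = 260L)
  cfg <- simulation_config(ref, panel, input_mass_ng = 3, recovery = 0.221,
                           family_size_mean = 5,
                           raw_substitution_rate = 1e-3,
                           raw_indel_rate = 0, tag_error_rate = 0)
  sim <- simulate_sample(cfg, seed = 13L)
  sscs <- collapse_families(sim$reads)
  pile <- build_pileup(sscs, panel, ref)
  raw <- error_rate(sim$reads, ref, panel, level = "raw")
  cons <- error_rate(pile, ref, panel, level = "sscs")
  expect_gt(raw$rate, 0)
  expect_lt(cons$rate, raw$rate)
})
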