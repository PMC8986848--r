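# Binomial tail test, Bonferroni control, strand bias, filter chain, VAF

test_that("binomial tail test matches the frozen exact value and the edge", {
  expect_equal(test_position(0L, 165L, 0.001), 1)
  # P(X >= 3 | n = 165, eps = 0.001), frozen from the exhaustive pmf oracle
  expect_equal(test_position(3L, 165L, 0.001), 6.513166e-4,
               tolerance = 1e-6)
  expect_equal(test_position(3L, 165L, 0.001),
               oracle_binom_tail(3L, 165L, 0.001), tolerance = 1e-12)
  expect_error(test_position(1L, 10L, 1.5), "epsilon_up")
})

test_that("survival function agrees with exhaustive pmf summation", {
  for (eps in c(1e-4, 1e-3, 0.01, 0.1, 0.5)) {
    for (n in c(1L, 2L, 5L, 17L, 33L, 50L)) {
      k <- 0:n
      got <- test_position(k, n, eps)
      want <- vapply(k, oracle_binom_tail, 1, n = n, p = eps)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("Bonferroni adjustment scales, clips and preserves order", {
  expect_equal(bonferroni_adjust(0.001, 10L), 0.01)
  expect_equal(bonferroni_adjust(0.5, 1000L), 1)
  set.seed(201)
  p <- sort(runif(50))
  adj <- bonferroni_adjust(p, 500L)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_error(bonferroni_adjust(0.1, 0L), "m must be")
  expect_error(bonferroni_adjust(runif(10), 5L), "m must cover")
})

test_that("strand-bias exact test: balance, extremes, symmetry", {
  expect_equal(strand_bias_test(5L, 5L, 100L, 100L), 1)
  # 10 alt on one strand at 1000/1000: the exact two-sided p is ~1.9e-3
  # (both one-sided extremes are equally probable and pool)
  expect_equal(strand_bias_test(10L, 0L, 1000L, 1000L),
               stats::fisher.test(matrix(c(10L, 990L, 0L, 1000L), 2L,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
  expect_lt(strand_bias_test(13L, 0L, 1000L, 1000L), 0.001)
  # symmetric under swapping strand labels
  set.seed(211)
  for (i in 1:20) {
    cf <- sample(50:500, 1L); cr <- sample(50:500, 1L)
    af <- sample(0:20, 1L); ar <- sample(0:20, 1L)
    expect_equal(strand_bias_test(af, ar, cf, cr),
                 strand_bias_test(ar, af, cr, cf), tolerance = 1e-12)
  }
})

test_that("strand-bias test agrees with the independent exact-test oracle", {
  set.seed(221)
  for (i in 1:40) {
    cf <- sample(10:300, 1L); cr <- sample(10:300, 1L)
    af <- sample(0:min(15L, cf), 1L); ar <- sample(0:min(15L, cr), 1L)
    got <- strand_bias_test(af, ar, cf, cr)
    want <- stats::fisher.test(matrix(c(af, cf - af, ar, cr - ar), 2L,
                                      byrow = TRUE))$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("VAF is the exact supporting fraction", {
  expect_equal(compute_vaf(3L, 165L), 3 / 165)
  expect_equal(sprintf("%.1f%%", 100 * compute_vaf(3L, 165L)), "1.8%")
  expect_equal(compute_vaf(0L, 100L), 0)
  expect_equal(compute_vaf(100L, 100L), 1)
  expect_error(compute_vaf(1L, 0L), "coverage")
})

# -- caller scenarios on crafted pileups ---------------------------------

caller_fixture <- function(n_ref = 400L, n_alt = 12L, alt_strands = NULL,
                           seed = 231L) {
  ref <- tiny_reference(40L, seed = 501L)
  panel <- tibble(chrom = "chrT", start = 15L, end = 25L)
  pos <- 20L
  ref_base <- substr(ref[[1]], pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  set.seed(seed)
  strands <- c(rep(c("+", "-"), length.out = n_ref),
               alt_strands %||% rep(c("+", "-"), length.out = n_alt))
  reads <- make_reads(
    bases = c(rep(ref_base, n_ref), rep(alt, n_alt)),
    tag = random_tags(n_ref + n_alt), chrom = "chrT", start = pos,
    strand = strands)
  sample_pile <- build_pileup(
    collapse_families(reads, consensus_config(tag_merge_hamming = 0L)),
    panel, ref)
  # deep error-free controls across the whole panel for the profile
  controls <- lapply(1:2, function(i) {
    ctrl <- make_reads(bases = rep(substr(ref[[1]], 16L, 25L), 500L),
                       tag = random_tags(500L), start = 15L,
                       read_id = paste0("c", i, "_", 1:500),
                       strand = rep(c("+", "-"), length.out = 500L))
    build_pileup(collapse_families(ctrl, consensus_config(tag_merge_hamming = 0L)),
                 panel, ref)
  })
  profile <- build_error_profile(controls, profile_config())
  list(ref = ref, panel = panel, pos = pos, alt = alt,
       sample = sample_pile, profile = profile)
}

test_that("a well-supported variant is called PASS with its exact VAF", {
  fx <- caller_fixture(n_ref = 400L, n_alt = 12L)
  res <- call_variants(fx$sample, fx$profile, caller_config())
  pass <- pass_calls(res)
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$pos, fx$pos)
  expect_equal(pass$alt, fx$alt)
  expect_equal(pass$vaf, (pass$alt_f + pass$alt_r) / pass$coverage)
  expect_lt(pass$p_adj, 0.05)
  # the universe counts every testable hypothesis, not just candidates
  expect_equal(res$m, 3L * res$n_tested_positions)
})

test_that("single-strand support is filtered with reason", {
  fx <- caller_fixture(n_alt = 12L, alt_strands = rep("+", 12L))
  res <- call_variants(fx$sample, fx$profile, caller_config())
  expect_equal(nrow(pass_calls(res)), 0L)
  hit <- res$calls |> filter(pos == fx$pos, alt == fx$alt)
  expect_true(grepl("single_strand", hit$filter))
})

test_that("extreme strand imbalance fails the bias filter even with both strands", {
  fx <- caller_fixture(n_alt = 40L, alt_strands = c(rep("+", 39L), "-"))
  res <- call_variants(fx$sample, fx$profile,
                       caller_config(strand_bias_p_floor = 0.001))
  hit <- res$calls |> filter(pos == fx$pos, alt == fx$alt)
  expect_true(grepl("strand_bias", hit$filter))
  expect_equal(nrow(pass_calls(res)), 0L)
})

test_that("SNP-masked positions are never tested", {
  fx <- caller_fixture()
  cfg <- caller_config(snp_mask = tibble(chrom = "chrT", pos = fx$pos))
  res <- call_variants(fx$sample, fx$profile, cfg)
  expect_equal(nrow(res$calls |> filter(pos == fx$pos)), 0L)
  # masked position leaves the Bonferroni universe
  res_unmasked <- call_variants(fx$sample, fx$profile, caller_config())
  expect_equal(res_unmasked$m - res$m, 3L)
})

test_that("positions below the coverage floor are not considered", {
  fx <- caller_fixture(n_ref = 60L, n_alt = 30L)   # coverage 90 < 100
  res <- call_variants(fx$sample, fx$profile, caller_config())
  expect_equal(nrow(res$calls |> filter(pos == fx$pos)), 0L)
  relaxed <- call_variants(fx$sample, fx$profile,
                           caller_config(min_sscs_coverage = 50L))
  expect_gt(nrow(pass_calls(relaxed)), 0L)
})

indel_fixture <- function(del_len, n_alt = 12L, seed = 241L) {
  ref <- tiny_reference(60L, seed = 511L)
  panel <- tibble(chrom = "chrT", start = 10L, end = 50L)
  set.seed(seed)
  template <- substr(ref[[1]], 11L, 50L)     # 40 bp, starts at pos 10
  del_bases <- paste0(substr(template, 1L, 10L),
                      substr(template, 11L + del_len, 40L))
  del_cigar <- paste0("10M", del_len, "D", 30L - del_len, "M")
  n_ref <- 400L
  reads <- bind_rows(
    make_reads(bases = rep(template, n_ref), tag = random_tags(n_ref),
               start = 10L, strand = rep(c("+", "-"), length.out = n_ref)),
    make_reads(bases = rep(del_bases, n_alt), tag = random_tags(n_alt),
               start = 10L, cigar = del_cigar,
               strand = rep(c("+", "-"), length.out = n_alt),
               read_id = paste0("d", seq_len(n_alt)))
  )
  sample_pile <- build_pileup(
    collapse_families(reads, consensus_config(tag_merge_hamming = 0L)),
    panel, ref)
  controls <- lapply(1:2, function(i) {
    ctrl <- make_reads(bases = rep(template, 500L), tag = random_tags(500L),
                       start = 10L, read_id = paste0("c", i, "_", 1:500),
                       strand = rep(c("+", "-"), length.out = 500L))
    build_pileup(collapse_families(ctrl, consensus_config(tag_merge_hamming = 0L)),
                 panel, ref)
  })
  profile <- build_error_profile(controls, profile_config())
  list(ref = ref, panel = panel, sample = sample_pile, profile = profile)
}

test_that("2-base deletions are excluded; 3-base deletions are tested and called", {
  fx2 <- indel_fixture(del_len = 2L)
  res2 <- call_variants(fx2$sample, fx2$profile, caller_config())
  short <- res2$calls |> filter(type == "del")
  expect_true(all(short$filter == "indel_too_short"))
  expect_true(all(is.na(short$p_adj)))
  expect_equal(nrow(pass_calls(res2) |> filter(type == "del")), 0L)

  fx3 <- indel_fixture(del_len = 3L)
  res3 <- call_variants(fx3$sample, fx3$profile, caller_config())
  called <- pass_calls(res3) |> filter(type == "del")
  expect_equal(nrow(called), 1L)
  expect_equal(called$length, 3L)
})

test_that("calling is deterministic for fixed inputs", {
  fx <- caller_fixture()
  a <- call_variants(fx$sample, fx$profile, caller_config())
  b <- call_variants(fx$sample, fx$profile, caller_config())
  expect_identical(a$calls, b$calls)
  expect_identical(a$m, b$m)
})

test_that("relaxing any filter never reduces the number of PASS calls", {
  fx <- caller_fixture(n_alt = 12L, alt_strands = rep("+", 12L))
  strict <- call_variants(fx$sample, fx$profile, caller_config())
  no_strand <- call_variants(fx$sample, fx$profile,
                             caller_config(require_both_strands = FALSE))
  no_bias <- call_variants(fx$sample, fx$profile,
                           caller_config(strand_bias_p_floor = 0))
  expect_gte(nrow(pass_calls(no_strand)), nrow(pass_calls(strict)))
  expect_gte(nrow(pass_calls(no_bias)), nrow(pass_calls(strict)))
})

test_that("calls serialise to VCF v4.2 with typed header and records", {
  fx <- caller_fixture()
  res <- call_variants(fx$sample, fx$profile, caller_config())
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(res, path, fx$ref)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("^#CHROM\tPOS\tID\tREF\tALT", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), nrow(res$calls))
  pass_row <- strsplit(body[grepl("\tPASS\t", body)][1], "\t")[[1]]
  expect_equal(pass_row[4], substr(fx$ref[[1]], fx$pos + 1L, fx$pos + 1L))
  expect_equal(pass_row[5], fx$alt)
  expect_equal(as.integer(pass_row[2]), fx$pos + 1L)
  expect_match(pass_row[8], "VAF=")
})

test_that("tidy and glance summarise a call set", {
  fx <- caller_fixture()
  res <- call_variants(fx$sample, fx$profile, caller_config())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$pos, res$calls$pos + 1L)
  gl <- glance(res)
  expect_equal(gl$n_pass, 1L)
  expect_equal(gl$m, res$m)
})
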