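# Evaluation metrics: substitution error rates at the raw-read, consensus
# and called levels; molecular recovery; VAF concordance between methods.

# Substitution mismatch counts of raw reads against the reference over
# panel positions (M-aligned bases only; indels and N bases excluded).
raw_mismatch_counts <- function(reads, reference, panel, snp_mask = NULL) {
  reference <- as_reference(reference)
  pp <- panel_positions(panel)
  masked <- in_position_set(pp$chrom, pp$pos, snp_mask)
  pp <- pp[!masked, , drop = FALSE]
  errors <- 0L; bases <- 0L
  if (nrow(reads) > 0L) {
    pure <- grepl("^\\d+M$", reads$cigar)
    pieces <- list()
    if (any(pure)) {
      lens <- nchar(reads$bases[pure])
      pieces$fast <- tibble(
        chrom = rep.int(reads$chrom[pure], lens),
        pos = rep.int(reads$start[pure], lens) + sequence(lens) - 1L,
        allele = unlist(strsplit(reads$bases[pure], "", fixed = TRUE),
                        use.names = FALSE))
    }
    if (any(!pure)) {
      pieces$slow <- bind_rows(purrr::map(which(!pure), function(i) {
        e <- expand_alignment(reads$bases[i], reads$start[i], reads$cigar[i])
        keep <- e$allele %in% DNA_BASES
        tibble(chrom = reads$chrom[i], pos = e$pos[keep],
               allele = e$allele[keep])
      }))
    }
    long <- bind_rows(pieces)
    long <- long[long$allele %in% DNA_BASES, , drop = FALSE]
    keep <- in_position_set(long$chrom, long$pos, pp)
    long <- long[keep, , drop = FALSE]
    key <- match(paste(long$chrom, long$pos), paste(pp$chrom, pp$pos))
    ref_allele <- substr(reference[pp$chrom[key]], pp$pos[key] + 1L,
                         pp$pos[key] + 1L)
    bases <- nrow(long)
    errors <- sum(long$allele != ref_allele)
  }
  list(errors = as.integer(errors), bases = as.integer(bases))
}

#' Substitution error rate at a processing level
#'
#' Counts non-reference substitution bases over the panel, with SNP-masked
#' positions excluded; indels are never counted. The three levels mirror
#' the pipeline stages:
#' * `"raw"` — `x` is a tagged-read tibble; errors are mismatched M-aligned
#'   read bases, the denominator all M-aligned read bases on the panel.
#' * `"sscs"` — `x` is an `sscs_pileup`; errors are non-reference A/C/G/T
#'   consensus counts, the denominator all A/C/G/T consensus counts.
#' * `"called"` — `x` is a list of `variant_calls` over mutation-free
#'   samples; errors are the summed alternative counts of PASS SNV calls,
#'   the denominator panel positions times samples (a per-base false-call
#'   rate).
#'
#' @param x input for the level (see above)
#' @param reference reference accepted by [as_reference()]
#' @param panel panel tibble (must be non-empty)
#' @param level `"raw"`, `"sscs"` or `"called"`
#' @param snp_mask optional tibble `chrom`, `pos`
#' @return tibble `level`, `errors`, `bases`, `rate`
#' @export
error_rate <- function(x, reference, panel, level = c("raw", "sscs", "called"),
                       snp_mask = NULL) {
  level <- match.arg(level)
  assert_that(nrow(panel) > 0L, "empty panel")
  if (level == "raw") {
    res <- raw_mismatch_counts(x, reference, panel, snp_mask)
    errors <- res$errors; bases <- res$bases
  } else if (level == "sscs") {
    tb <- as_tibble(x)
    masked <- in_position_set(tb$chrom, tb$pos, snp_mask)
    tb <- tb[!masked, , drop = FALSE]
    alt_of <- function(b) (tb[[paste0(b, "_f")]] + tb[[paste0(b, "_r")]]) *
      (tb$ref != b)
    errors <- sum(vapply(DNA_BASES, function(b) sum(alt_of(b)), 1))
    bases <- sum(vapply(DNA_BASES, function(b)
      sum(tb[[paste0(b, "_f")]] + tb[[paste0(b, "_r")]]), 1))
  } else {
    assert_that(is.list(x) && all(purrr::map_lgl(x, inherits, "variant_calls")),
                "called level needs a list of variant_calls objects")
    pass <- bind_rows(purrr::map(x, pass_calls))
    pass <- filter(pass, .data$type == "snv")
    errors <- sum(pass$alt_f + pass$alt_r)
    pp <- panel_positions(panel)
    masked <- in_position_set(pp$chrom, pp$pos, snp_mask)
    bases <- sum(!masked) * length(x)
  }
  tibble(level = level, errors = as.integer(errors),
         bases = as.integer(bases),
         rate = ifelse(bases > 0, errors / bases, 0))
}

#' Molecular recovery of a sample
#'
#' Fraction of input single-stranded molecules represented by a consensus
#' sequence. Input molecules are `2 * input_mass_ng / 0.0033` (two single
#' strands per genome equivalent at 3.3 pg per haploid genome); recovered
#' molecules are the median SSCS coverage over the panel. The constants are
#' echoed in the report.
#'
#' @param sscs_pileup an `sscs_pileup`
#' @param input_mass_ng cfDNA input mass in ng (> 0)
#' @return one-row tibble `input_mass_ng`, `genome_equivalents`,
#'   `input_molecules`, `recovered_molecules`, `recovery`,
#'   `ng_per_haploid_genome`, `strands_per_genome`
#' @export
molecular_recovery <- function(sscs_pileup, input_mass_ng) {
  assert_that(input_mass_ng > 0, "input_mass_ng must be positive")
  ge <- input_mass_ng / NG_PER_HAPLOID_GENOME
  input_molecules <- 2 * ge
  recovered <- median(as_tibble(sscs_pileup)$coverage)
  tibble(
    input_mass_ng = input_mass_ng,
    genome_equivalents = ge,
    input_molecules = input_molecules,
    recovered_molecules = recovered,
    recovery = recovered / input_molecules,
    ng_per_haploid_genome = NG_PER_HAPLOID_GENOME,
    strands_per_genome = 2L
  )
}

#' VAF concordance between two methods
#'
#' Spearman rank correlation (ranks correlated with Pearson's formula)
#' plus Bland-Altman agreement: bias is the mean difference `a - b`,
#' limits of agreement are `bias +/- 2 SD` of the differences.
#'
#' @param pairs tibble or data frame with columns `vaf_a`, `vaf_b` (at
#'   least 3 pairs)
#' @return one-row tibble `n`, `rank_correlation`, `bias`, `loa_lower`,
#'   `loa_upper`
#' @export
vaf_concordance <- function(pairs) {
  assert_that(nrow(pairs) >= 3L, "need at least 3 VAF pairs")
  a <- pairs$vaf_a; b <- pairs$vaf_b
  rho <- cor(rank(a), rank(b))
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  tibble(n = nrow(pairs), rank_correlation = rho, bias = bias,
         loa_lower = bias - 2 * s, loa_upper = bias + 2 * s)
}
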