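# De novo variant calling on a sample SSCS pileup against the background
# error profile: one-sided binomial tail tests per (position, alternative
# allele), Bonferroni control of the family-wise false-positive rate over
# everything that could have been called, and the filter chain (minimum
# SSCS coverage 100, dual-strand support, strand-bias exact test, minimum
# indel length 3, SNP masking).

#' Caller configuration
#'
#' @param alpha global (family-wise) false-positive level; a wild-type
#'   sample is declared mutated with probability below `alpha`
#' @param min_sscs_coverage positions with SSCS coverage below this are not
#'   considered for variant calling
#' @param require_both_strands demand at least one supporting consensus
#'   molecule on each strand
#' @param strand_bias_p_floor candidates whose two-sided strand-bias exact
#'   test gives `p < strand_bias_p_floor` fail the `strand_bias` filter
#' @param min_indel_length indels shorter than this are excluded (default
#'   3: only indels longer than 2 bases are considered)
#' @param snp_mask tibble `chrom`, `pos` (0-based) of known-SNP positions
#'   excluded from testing, or `NULL`
#' @return a `caller_config` list
#' @export
caller_config <- function(alpha = 0.05,
                          min_sscs_coverage = 100L,
                          require_both_strands = TRUE,
                          strand_bias_p_floor = 0.001,
                          min_indel_length = 3L,
                          snp_mask = NULL) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(min_sscs_coverage >= 1L, "min_sscs_coverage must be >= 1")
  assert_that(min_indel_length >= 1L, "min_indel_length must be >= 1")
  structure(list(alpha = alpha,
                 min_sscs_coverage = as.integer(min_sscs_coverage),
                 require_both_strands = isTRUE(require_both_strands),
                 strand_bias_p_floor = strand_bias_p_floor,
                 min_indel_length = as.integer(min_indel_length),
                 snp_mask = snp_mask),
            class = "caller_config")
}

#' One-sided binomial tail test against a background rate
#'
#' Returns `P(X >= alt_count)` for `X ~ Binomial(coverage, epsilon_up)`,
#' computed with the numerically stable survival function. Vectorised.
#'
#' @param alt_count observed alternative-allele consensus count
#' @param coverage SSCS coverage at the position
#' @param epsilon_up background (upper-bound) error rate in \[0, 1\]
#' @return upper-tail p-value(s)
#' @export
test_position <- function(alt_count, coverage, epsilon_up) {
  assert_that(all(coverage >= 1), "coverage must be >= 1")
  assert_that(all(alt_count >= 0 & alt_count <= coverage),
              "alt_count must satisfy 0 <= alt_count <= coverage")
  assert_that(all(epsilon_up >= 0 & epsilon_up <= 1),
              "epsilon_up must be in [0, 1]")
  pbinom(alt_count - 1, coverage, epsilon_up, lower.tail = FALSE)
}

#' Bonferroni adjustment over the tested universe
#'
#' `p_adj = min(1, m * p_raw)`, where `m` counts every (position,
#' alternative allele) hypothesis that met the testing criteria — not just
#' the candidates with nonzero alternative counts.
#'
#' @param p_values raw p-values
#' @param m size of the tested universe (`m >= length(p_values)`)
#' @return adjusted p-values, order-preserving
#' @export
bonferroni_adjust <- function(p_values, m) {
  assert_that(m >= 1, "m must be >= 1")
  assert_that(m >= length(p_values),
              "m must cover at least the candidate hypotheses")
  pmin(1, m * p_values)
}

#' Two-sided exact strand-bias test
#'
#' Exact two-sided test of equal alt-vs-reference proportions between
#' strands on the 2x2 table `[[alt_f, cov_f - alt_f], [alt_r, cov_r -
#' alt_r]]` (hypergeometric enumeration, summing all tables with
#' probability not exceeding the observed one). Symmetric under swapping
#' strand labels.
#'
#' @param alt_f,alt_r alternative-allele consensus counts per strand
#' @param cov_f,cov_r SSCS coverage per strand
#' @return two-sided p-value(s); vectorised
#' @export
strand_bias_test <- function(alt_f, alt_r, cov_f, cov_r) {
  assert_that(all(c(alt_f, alt_r, cov_f, cov_r) >= 0),
              "counts must be nonnegative")
  assert_that(all(alt_f <= cov_f & alt_r <= cov_r),
              "alt counts cannot exceed strand coverage")
  assert_that(all(cov_f + cov_r >= 1), "total coverage must be >= 1")
  purrr::pmap_dbl(list(alt_f, alt_r, cov_f, cov_r), function(af, ar, cf, cr) {
    k <- af + ar
    support <- max(0, k - cr):min(k, cf)
    pr <- stats::dhyper(support, cf, cr, k)
    obs <- stats::dhyper(af, cf, cr, k)
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  })
}

#' Variant allele frequency
#' @param alt_total total alternative consensus count (both strands)
#' @param coverage total SSCS coverage
#' @return `alt_total / coverage`
#' @export
compute_vaf <- function(alt_total, coverage) {
  assert_that(all(coverage >= 1), "coverage must be >= 1 (zero-coverage
    positions have no VAF)")
  assert_that(all(alt_total >= 0 & alt_total <= coverage),
              "alt_total must satisfy 0 <= alt_total <= coverage")
  alt_total / coverage
}

# Long candidate view of a sample pileup: SNV alts with nonzero counts
snv_candidates <- function(pileup) {
  tb <- as_tibble(pileup)
  out <- purrr::map(DNA_BASES, function(b) {
    f <- tb[[paste0(b, "_f")]]
    r <- tb[[paste0(b, "_r")]]
    keep <- (f + r) > 0L & tb$ref != b
    tibble(chrom = tb$chrom[keep], pos = tb$pos[keep], ref = tb$ref[keep],
           alt = b, type = "snv", length = 1L, seq = b,
           alt_f = f[keep], alt_r = r[keep],
           cov_f = tb$cov_f[keep], cov_r = tb$cov_r[keep],
           coverage = tb$coverage[keep])
  })
  bind_rows(out)
}

indel_candidates <- function(pileup) {
  ev <- attr(pileup, "indel_events")
  if (is.null(ev) || nrow(ev) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), type = character(), length = integer(),
                  seq = character(), alt_f = integer(), alt_r = integer(),
                  cov_f = integer(), cov_r = integer(), coverage = integer()))
  }
  cov <- select(as_tibble(pileup), "chrom", "pos", "ref",
                "cov_f", "cov_r", "coverage")
  ev |>
    group_by(.data$chrom, .data$pos, .data$type, .data$length) |>
    summarise(alt_f = sum(.data$count[.data$strand == "+"]),
              alt_r = sum(.data$count[.data$strand == "-"]),
              seq = .data$seq[which.max(.data$count)],
              .groups = "drop") |>
    inner_join(cov, by = c("chrom", "pos")) |>
    mutate(alt = paste0(.data$type, ":", .data$length)) |>
    select("chrom", "pos", "ref", "alt", "type", "length", "seq",
           "alt_f", "alt_r", "cov_f", "cov_r", "coverage")
}

#' Call variants on a sample pileup against an error profile
#'
#' Every non-SNP panel position with SSCS coverage at or above
#' `min_sscs_coverage` and background coverage in the profile defines three
#' SNV hypotheses (one per alternative allele); indel classes of length at
#' least `min_indel_length` observed in the sample add one hypothesis each.
#' Their total is the Bonferroni universe `m`. Candidates with nonzero
#' alternative counts receive a binomial tail p-value against the profile's
#' `epsilon_up`; candidates significant after adjustment (`p_adj < alpha`,
#' strict) are emitted, labelled by any failed filters (`single_strand`,
#' `strand_bias`); an empty filter set is `PASS`. Indel candidates shorter
#' than `min_indel_length` are emitted untested with filter
#' `indel_too_short`. Positions below the coverage floor or inside the SNP
#' mask are not considered at all. The result is a deterministic function
#' of (pileup, profile, config).
#'
#' @param sample an `sscs_pileup` for the tested sample
#' @param profile an `error_profile` built over the same panel
#' @param cfg a [caller_config()]
#' @return a `variant_calls` object: list with `calls` (tibble: `chrom`,
#'   `pos` 0-based, `ref`, `alt`, `type`, `length`, `seq`, `alt_f`,
#'   `alt_r`, `coverage`, `vaf`, `p_raw`, `p_adj`, `p_bias`, `filter`),
#'   `m`, `alpha`, `n_tested_positions`, `config`
#' @export
call_variants <- function(sample, profile, cfg = caller_config()) {
  tb <- as_tibble(sample)
  pos_cov <- attr(profile, "position_coverage")
  assert_that(!is.null(pos_cov), "profile lacks position coverage metadata")
  in_profile <- paste(tb$chrom, tb$pos) %in% paste(pos_cov$chrom, pos_cov$pos)
  assert_that(all(paste(pos_cov$chrom, pos_cov$pos) %in%
                    paste(tb$chrom, tb$pos)),
              "profile/panel mismatch: profile positions missing from sample")
  masked <- in_position_set(tb$chrom, tb$pos, cfg$snp_mask)
  qual <- tb$coverage >= cfg$min_sscs_coverage & !masked & in_profile
  qual_key <- paste(tb$chrom, tb$pos)[qual]

  cand <- bind_rows(snv_candidates(sample), indel_candidates(sample)) |>
    filter(paste(.data$chrom, .data$pos) %in% qual_key)

  short_indel <- cand$type != "snv" & cand$length < cfg$min_indel_length
  excluded <- cand[short_indel, , drop = FALSE]
  cand <- cand[!short_indel, , drop = FALSE]

  n_indel_hyp <- sum(cand$type != "snv")
  m <- 3L * sum(qual) + n_indel_hyp

  delta <- attr(profile, "delta") %||% 0.01
  ub <- upper_bound_fun(attr(profile, "bound_method") %||% "exact")

  calls <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), type = character(), length = integer(),
                  seq = character(), alt_f = integer(), alt_r = integer(),
                  coverage = integer(), vaf = numeric(), p_raw = numeric(),
                  p_adj = numeric(), p_bias = numeric(), filter = character())
  if (nrow(cand) > 0L && m >= 1L) {
    prof <- as_tibble(profile)[, c("chrom", "pos", "alt", "k", "n",
                                   "epsilon_up")]
    cand <- cand |>
      left_join(prof, by = c("chrom", "pos", "alt")) |>
      left_join(rename(pos_cov, n_pos = "n")[, c("chrom", "pos", "n_pos")],
                by = c("chrom", "pos"))
    # indel classes never seen in controls: k = 0 against the position's
    # pooled background coverage
    miss <- is.na(cand$epsilon_up)
    if (any(miss)) {
      cand$epsilon_up[miss] <- ub(0L, cand$n_pos[miss], delta)
    }
    cand <- cand |>
      mutate(
        alt_total = .data$alt_f + .data$alt_r,
        vaf = compute_vaf(.data$alt_total, .data$coverage),
        p_raw = test_position(.data$alt_total, .data$coverage,
                              .data$epsilon_up),
        p_adj = bonferroni_adjust(.data$p_raw, m)
      ) |>
      filter(.data$p_adj < cfg$alpha)
    if (nrow(cand) > 0L) {
      cand <- cand |>
        mutate(
          p_bias = strand_bias_test(.data$alt_f, .data$alt_r,
                                    .data$cov_f, .data$cov_r),
          fail_strand = cfg$require_both_strands &
            (.data$alt_f < 1L | .data$alt_r < 1L),
          fail_bias = .data$p_bias < cfg$strand_bias_p_floor,
          filter = purrr::map2_chr(.data$fail_strand, .data$fail_bias,
            function(s, b) {
              lab <- c(if (s) "single_strand", if (b) "strand_bias")
              if (length(lab) == 0L) "PASS" else paste(lab, collapse = ";")
            })
        )
      calls <- select(cand, "chrom", "pos", "ref", "alt", "type", "length",
                      "seq", "alt_f", "alt_r", "coverage", "vaf", "p_raw",
                      "p_adj", "p_bias", "filter")
    }
  }
  if (nrow(excluded) > 0L) {
    excluded <- excluded |>
      mutate(vaf = compute_vaf(.data$alt_f + .data$alt_r, .data$coverage),
             p_raw = NA_real_, p_adj = NA_real_, p_bias = NA_real_,
             filter = "indel_too_short") |>
      select(dplyr::all_of(names(calls)))
    calls <- bind_rows(calls, excluded)
  }
  calls <- arrange(calls, .data$chrom, .data$pos, .data$alt)
  structure(list(calls = calls, m = m, alpha = cfg$alpha,
                 n_tested_positions = sum(qual), config = cfg),
            class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  np <- sum(x$calls$filter == "PASS")
  cat(sprintf(
    "<variant_calls> %d PASS / %d emitted; m = %d hypotheses over %d positions (alpha = %g)\n",
    np, nrow(x$calls), x$m, x$n_tested_positions, x$alpha))
  if (nrow(x$calls) > 0L) print(as_tibble(x$calls), ...)
  invisible(x)
}

#' PASS calls of a `variant_calls` object
#' @param x a `variant_calls` object
#' @return tibble of PASS calls
#' @export
pass_calls <- function(x) {
  filter(x$calls, .data$filter == "PASS")
}
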