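# Background error profile from mutation-free control samples: per
# (position, alternative allele) counts pooled across controls, with a
# conservative upper confidence bound on the error rate so that positions
# where no error was ever observed still receive a strictly positive rate.

#' Error-profile configuration
#'
#' @param delta per-(position, allele) confidence level of the upper bound:
#'   the probability that the bound falls below the true error rate is at
#'   most `delta`
#' @param bound_method `"exact"` (Clopper-Pearson one-sided binomial upper
#'   bound, the default) or `"massart"` (additive sub-Gaussian concentration
#'   bound `k/n + sqrt(ln(1/delta)/(2n))`)
#' @param pool_strands pool forward and reverse counts in the profile
#'   (strand balance is enforced separately by the caller); `FALSE` is not
#'   currently implemented
#' @param snp_mask tibble `chrom`, `pos` (0-based) of known-SNP positions
#'   excluded from profiling, or `NULL`
#' @return a `profile_config` list
#' @export
profile_config <- function(delta = 0.01,
                           bound_method = c("exact", "massart"),
                           pool_strands = TRUE,
                           snp_mask = NULL) {
  assert_that(delta > 0 && delta < 1, "delta must be in (0, 1)")
  assert_that(isTRUE(pool_strands), "only pooled-strand profiles are supported")
  structure(list(delta = delta, bound_method = match.arg(bound_method),
                 pool_strands = pool_strands, snp_mask = snp_mask),
            class = "profile_config")
}

#' Additive concentration upper bound on a binomial proportion
#'
#' `k/n + sqrt(ln(1/delta) / (2n))`, clipped to 1 — the sub-Gaussian
#' (Hoeffding-type, sharp-constant) bound. Strictly positive even at
#' `k = 0`, nonincreasing in `n` for fixed `k/n`, and always at least the
#' maximum-likelihood rate `k/n`.
#'
#' @param k observed error count (vectorised)
#' @param n trials; `n = 0` is an error (`"no_coverage"`)
#' @param delta confidence level
#' @return upper-bound rate(s) in (0, 1]
#' @export
massart_upper_bound <- function(k, n, delta = 0.01) {
  assert_that(all(n >= 1), "no_coverage: n must be >= 1")
  assert_that(all(k >= 0 & k <= n), "k must satisfy 0 <= k <= n")
  pmin(1, k / n + sqrt(log(1 / delta) / (2 * n)))
}

#' Exact binomial (Clopper-Pearson) one-sided upper bound
#'
#' The smallest rate `p` with `P(X <= k | n, p) <= delta`, i.e.
#' `qbeta(1 - delta, k + 1, n - k)`. Much tighter than the additive bound
#' at large `n` with small `k` (for `k = 0` it behaves like
#' `ln(1/delta)/n`), while keeping the same coverage guarantee.
#'
#' @inheritParams massart_upper_bound
#' @return upper-bound rate(s) in (0, 1]
#' @export
exact_upper_bound <- function(k, n, delta = 0.01) {
  assert_that(all(n >= 1), "no_coverage: n must be >= 1")
  assert_that(all(k >= 0 & k <= n), "k must satisfy 0 <= k <= n")
  qbeta(1 - delta, k + 1, pmax(n - k, 1e-9))
}

upper_bound_fun <- function(method) {
  switch(method, exact = exact_upper_bound, massart = massart_upper_bound,
         abort(paste0("unknown bound method: ", method)))
}

# Candidate (position, alt) long view of one pileup, strand-pooled:
# SNV alts (3 per position) plus observed indel classes.
pileup_background_long <- function(pileup) {
  base <- as_tibble(pileup) |>
    select("chrom", "pos", "ref", "A_f", "A_r", "C_f", "C_r",
           "G_f", "G_r", "T_f", "T_r", "coverage")
  snv <- base |>
    tidyr::pivot_longer(cols = dplyr::matches("^[ACGT]_[fr]$"),
                        names_to = c("alt", "strand"), names_sep = "_",
                        values_to = "cnt") |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
             coverage = .data$coverage) |>
    summarise(k = sum(.data$cnt), .groups = "drop") |>
    filter(.data$alt != .data$ref) |>
    mutate(n = .data$coverage) |>
    select("chrom", "pos", "ref", "alt", "k", "n")
  ev <- attr(pileup, "indel_events")
  indel <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), k = integer(), n = integer())
  if (!is.null(ev) && nrow(ev) > 0L) {
    cov <- select(as_tibble(pileup), "chrom", "pos", "ref", "coverage")
    indel <- ev |>
      group_by(.data$chrom, .data$pos, .data$type, .data$length) |>
      summarise(k = sum(.data$count), .groups = "drop") |>
      mutate(alt = paste0(.data$type, ":", .data$length)) |>
      inner_join(cov, by = c("chrom", "pos")) |>
      mutate(n = .data$coverage) |>
      select("chrom", "pos", "ref", "alt", "k", "n")
  }
  bind_rows(snv, indel)
}

#' Accumulate background counts over control pileups
#'
#' Sums alt counts `k` and coverages `n` per (position, alternative allele)
#' across control samples, excluding SNP-masked positions. Indel background
#' is keyed by (position, indel type, length class) rather than exact
#' sequence. All pileups must cover the identical panel.
#'
#' @param control_pileups list of `sscs_pileup` objects
#' @param snp_mask tibble `chrom`, `pos` (0-based) or `NULL`
#' @return tibble `chrom`, `pos`, `ref`, `alt`, `k`, `n` (strand-pooled)
#' @export
accumulate_background <- function(control_pileups, snp_mask = NULL) {
  assert_that(length(control_pileups) >= 1L, "need at least one control")
  panels <- purrr::map(control_pileups,
                       ~ paste(.x$chrom, .x$pos, collapse = ";"))
  assert_that(length(unique(unlist(panels))) == 1L,
              "control pileups cover mismatched panels")
  long <- purrr::map(control_pileups, pileup_background_long)
  out <- bind_rows(long) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(k = sum(.data$k), n = sum(.data$n), .groups = "drop")
  masked <- in_position_set(out$chrom, out$pos, snp_mask)
  out[!masked, , drop = FALSE] |>
    arrange(.data$chrom, .data$pos, .data$alt)
}

#' Build the background error profile from control samples
#'
#' One entry per (panel position, alternative allele) with pooled coverage
#' `n > 0`, carrying the conservative upper-bound error rate `epsilon_up`.
#' The per-position total coverage across controls is attached as attribute
#' `"position_coverage"` so indel classes never observed in any control can
#' still be tested against a `k = 0` background.
#'
#' @param controls list of `sscs_pileup` objects (at least one)
#' @param cfg a [profile_config()]
#' @return an `error_profile` tibble: `chrom`, `pos`, `ref`, `alt`, `k`,
#'   `n`, `epsilon_up`; attributes `delta`, `bound_method`, `n_controls`,
#'   `position_coverage`
#' @export
build_error_profile <- function(controls, cfg = profile_config()) {
  assert_that(length(controls) >= 1L, "zero control samples")
  bg <- accumulate_background(controls, cfg$snp_mask)
  bg <- filter(bg, .data$n > 0L)
  ub <- upper_bound_fun(cfg$bound_method)
  out <- mutate(bg, epsilon_up = ub(.data$k, .data$n, cfg$delta))
  pos_cov <- out |>
    filter(!grepl(":", .data$alt)) |>
    distinct(.data$chrom, .data$pos, .data$ref, n = .data$n)
  attr(out, "delta") <- cfg$delta
  attr(out, "bound_method") <- cfg$bound_method
  attr(out, "n_controls") <- length(controls)
  attr(out, "position_coverage") <- pos_cov
  class(out) <- c("error_profile", class(tibble()))
  out
}

#' Write an error profile (TSV plus JSON sidecar)
#'
#' Rates are serialised at full double precision so save/load round-trips
#' are bit-exact. The sidecar records delta, the bound method, a panel
#' checksum and the tool version.
#'
#' @param profile an `error_profile`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_error_profile <- function(profile, path) {
  out <- as_tibble(profile) |>
    mutate(pos = .data$pos + 1L, epsilon_up = num_chr(.data$epsilon_up))
  readr::write_tsv(out, path)
  meta <- list(
    delta = attr(profile, "delta"),
    bound_method = attr(profile, "bound_method"),
    n_controls = attr(profile, "n_controls"),
    panel_checksum = rlang::hash(paste(profile$chrom, profile$pos)),
    tool_version = pkg_version()
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an error profile written by [write_error_profile()]
#' @param path TSV path
#' @return an `error_profile` tibble
#' @export
read_error_profile <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = "c", ref = "c", alt = "c",
                           pos = "i", k = "i", n = "i",
                           epsilon_up = "c")) |>
    # parse rates with strtod so %.17g serialisation round-trips bit-exactly
    mutate(pos = .data$pos - 1L, epsilon_up = as.numeric(.data$epsilon_up))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  pos_cov <- tbl |>
    filter(!grepl(":", .data$alt)) |>
    distinct(.data$chrom, .data$pos, .data$ref, n = .data$n)
  attr(tbl, "delta") <- meta$delta
  attr(tbl, "bound_method") <- meta$bound_method
  attr(tbl, "n_controls") <- meta$n_controls
  attr(tbl, "position_coverage") <- pos_cov
  class(tbl) <- c("error_profile", class(tibble()))
  tbl
}
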