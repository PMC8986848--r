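#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a variant-call result
#'
#' One row per emitted candidate, with 1-based positions for display.
#'
#' @param x a `variant_calls` object
#' @param ... unused
#' @return tibble of calls
#' @export
tidy.variant_calls <- function(x, ...) {
  mutate(x$calls, pos = .data$pos + 1L)
}

#' One-row summary of a variant-call result
#'
#' @param x a `variant_calls` object
#' @param ... unused
#' @return tibble with `n_pass`, `n_emitted`, `m`, `n_tested_positions`,
#'   `alpha`
#' @export
glance.variant_calls <- function(x, ...) {
  tibble(n_pass = sum(x$calls$filter == "PASS"),
         n_emitted = nrow(x$calls),
         m = x$m,
         n_tested_positions = x$n_tested_positions,
         alpha = x$alpha)
}

#' Tidy an error profile
#' @param x an `error_profile`
#' @param ... unused
#' @return tibble of profile entries (1-based positions)
#' @export
tidy.error_profile <- function(x, ...) {
  mutate(as_tibble(x), pos = .data$pos + 1L)
}

#' One-row summary of an error profile
#' @param x an `error_profile`
#' @param ... unused
#' @return tibble with entry counts and epsilon_up summaries
#' @export
glance.error_profile <- function(x, ...) {
  tibble(n_entries = nrow(x),
         n_positions = n_distinct(paste(x$chrom, x$pos)),
         n_controls = attr(x, "n_controls") %||% NA_integer_,
         delta = attr(x, "delta") %||% NA_real_,
         bound_method = attr(x, "bound_method") %||% NA_character_,
         mean_epsilon_up = mean(x$epsilon_up),
         frac_error_free = mean(x$k == 0))
}
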