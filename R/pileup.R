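# SSCS pileup: per-position, per-allele, per-strand counts at consensus
# level over the capture panel. Coverage at a position is the number of
# consensus molecules voting a concrete allele (A/C/G/T or deletion) there;
# N positions contribute nothing. Insertion events are anchored at the
# reference base they follow and are annotations on top of the per-position
# counts, not part of coverage.

ALLELE_LEVELS <- c("A", "C", "G", "T", "-")

new_pileup <- function(tbl, indel_events, n_sscs) {
  attr(tbl, "indel_events") <- indel_events
  attr(tbl, "n_sscs") <- n_sscs
  class(tbl) <- c("sscs_pileup", class(tibble()))
  tbl
}

empty_indel_events <- function() {
  tibble(chrom = character(), pos = integer(), type = character(),
         length = integer(), seq = character(), strand = character(),
         count = integer())
}

#' Pile up consensus sequences over a panel
#'
#' Accumulates per-position, per-allele, per-strand counts from consensus
#' records. `N` consensus bases contribute to neither allele counts nor
#' coverage; positions outside the panel are ignored. Deleted positions
#' (consensus `-`) count toward `del_*` and coverage. Consensus insertion
#' events are aggregated into the `"indel_events"` attribute together with
#' deletion events (anchored at their first deleted base).
#'
#' @param sscs an `sscs_records` tibble from [collapse_families()]
#' @param panel tibble `chrom`, `start`, `end` (0-based half-open)
#' @param reference reference accepted by [as_reference()]; every panel
#'   contig must be present
#' @return an `sscs_pileup` tibble with one row per panel position:
#'   `chrom`, `pos` (0-based), `ref`, `A_f`, `A_r`, `C_f`, `C_r`, `G_f`,
#'   `G_r`, `T_f`, `T_r`, `del_f`, `del_r`, `ins_f`, `ins_r`, `cov_f`,
#'   `cov_r`, `coverage`; attributes `"indel_events"` and `"n_sscs"`
#' @export
build_pileup <- function(sscs, panel, reference) {
  reference <- as_reference(reference)
  missing_contig <- setdiff(unique(panel$chrom), names(reference))
  assert_that(length(missing_contig) == 0L,
              paste0("panel contig absent from reference: ",
                     paste(missing_contig, collapse = ", ")))
  assert_that(nrow(panel) > 0L, "panel must not be empty")

  pp <- panel_positions(panel) |> distinct(.data$chrom, .data$pos)
  P <- nrow(pp)
  # per-contig map from 0-based position to row index of pp
  posmap <- list()
  for (ch in unique(pp$chrom)) {
    v <- integer(nchar(reference[[ch]]))
    rows <- which(pp$chrom == ch)
    v[pp$pos[rows] + 1L] <- rows
    posmap[[ch]] <- v
  }

  counts <- matrix(0L, nrow = P, ncol = 10L)  # 5 alleles x 2 strands
  if (nrow(sscs) > 0L) {
    lens <- nchar(sscs$bases)
    gpos <- rep.int(sscs$start, lens) + sequence(lens) - 1L
    gch <- rep.int(sscs$chrom, lens)
    gstr <- rep.int(sscs$strand, lens)
    gall <- unlist(strsplit(sscs$bases, "", fixed = TRUE), use.names = FALSE)

    gidx <- integer(length(gpos))
    for (ch in names(posmap)) {
      sel <- gch == ch & gpos < length(posmap[[ch]])
      gidx[sel] <- posmap[[ch]][gpos[sel] + 1L]
    }
    aidx <- match(gall, ALLELE_LEVELS)       # NA for N
    sidx <- ifelse(gstr == "+", 1L, 2L)
    keep <- gidx > 0L & !is.na(aidx)
    code <- (gidx[keep] - 1L) * 10L + (aidx[keep] - 1L) * 2L + sidx[keep]
    counts <- matrix(tabulate(code, nbins = P * 10L),
                     nrow = P, ncol = 10L, byrow = TRUE)
  }

  # deletion events from "-" runs
  del_ev <- empty_indel_events()
  with_del <- which(grepl("-", sscs$bases, fixed = TRUE))
  if (length(with_del) > 0L) {
    del_ev <- bind_rows(purrr::map(with_del, function(i) {
      d <- del_events_from_bases(sscs$bases[i], sscs$start[i])
      mutate(d, chrom = sscs$chrom[i], strand = sscs$strand[i])
    })) |>
      count(.data$chrom, .data$pos, .data$length, .data$strand,
            name = "count") |>
      mutate(type = "del",
             seq = purrr::pmap_chr(
               list(.data$chrom, .data$pos, .data$length),
               function(ch, p, l) ref_slice(reference, ch, p, p + l)))
  }
  ins <- attr(sscs, "insertions")
  ins_ev <- empty_indel_events()
  if (!is.null(ins) && nrow(ins) > 0L) {
    ins_ev <- ins |>
      count(.data$chrom, .data$pos, .data$seq, .data$strand, name = "count") |>
      mutate(type = "ins", length = nchar(.data$seq))
  }
  indel_events <- bind_rows(del_ev, ins_ev)
  if (nrow(indel_events) > 0L) {
    on_panel <- in_position_set(indel_events$chrom, indel_events$pos, pp)
    indel_events <- indel_events[on_panel, , drop = FALSE] |>
      select("chrom", "pos", "type", "length", "seq", "strand", "count") |>
      arrange(.data$chrom, .data$pos, .data$type, .data$length, .data$strand)
  } else {
    indel_events <- empty_indel_events()
  }

  # insertion per-anchor counts by strand
  ins_f <- ins_r <- integer(P)
  if (nrow(ins_ev) > 0L) {
    agg <- ins_ev |>
      group_by(.data$chrom, .data$pos, .data$strand) |>
      summarise(count = sum(.data$count), .groups = "drop")
    ridx <- match(paste(agg$chrom, agg$pos), paste(pp$chrom, pp$pos))
    ok <- !is.na(ridx)
    fwd <- ok & agg$strand == "+"
    rev <- ok & agg$strand == "-"
    ins_f[ridx[fwd]] <- agg$count[fwd]
    ins_r[ridx[rev]] <- agg$count[rev]
  }

  ref_allele <- substr(rep(reference[pp$chrom], 1L), pp$pos + 1L, pp$pos + 1L)
  out <- tibble(
    chrom = pp$chrom, pos = pp$pos, ref = unname(ref_allele),
    A_f = counts[, 1], A_r = counts[, 2],
    C_f = counts[, 3], C_r = counts[, 4],
    G_f = counts[, 5], G_r = counts[, 6],
    T_f = counts[, 7], T_r = counts[, 8],
    del_f = counts[, 9], del_r = counts[, 10],
    ins_f = ins_f, ins_r = ins_r
  ) |>
    mutate(
      cov_f = .data$A_f + .data$C_f + .data$G_f + .data$T_f + .data$del_f,
      cov_r = .data$A_r + .data$C_r + .data$G_r + .data$T_r + .data$del_r,
      coverage = .data$cov_f + .data$cov_r
    )
  new_pileup(out, indel_events, n_sscs = nrow(sscs))
}

PILEUP_TSV_COLS <- c("chrom", "pos", "ref", "A_f", "A_r", "C_f", "C_r",
                     "G_f", "G_r", "T_f", "T_r", "del_f", "del_r",
                     "ins_f", "ins_r", "coverage")

#' Write a pileup to TSV
#'
#' Positions are written 1-based. Indel events (needed to call indels and
#' to profile indel errors) go to a `<path>.indels.tsv` sidecar.
#'
#' @param pileup an `sscs_pileup`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_pileup <- function(pileup, path) {
  out <- as_tibble(pileup) |> mutate(pos = .data$pos + 1L)
  readr::write_tsv(out[, PILEUP_TSV_COLS], path)
  ev <- attr(pileup, "indel_events")
  if (is.null(ev)) ev <- empty_indel_events()
  readr::write_tsv(mutate(ev, pos = .data$pos + 1L),
                   paste0(path, ".indels.tsv"))
  meta <- list(n_sscs = attr(pileup, "n_sscs") %||% NA_integer_,
               tool_version = pkg_version())
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a pileup written by [write_pileup()]
#' @param path TSV path
#' @return an `sscs_pileup` tibble (positions 0-based again)
#' @export
read_pileup <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = "c", ref = "c",
                           .default = readr::col_integer())) |>
    mutate(pos = .data$pos - 1L,
           cov_f = .data$A_f + .data$C_f + .data$G_f + .data$T_f + .data$del_f,
           cov_r = .data$A_r + .data$C_r + .data$G_r + .data$T_r + .data$del_r)
  ev_path <- paste0(path, ".indels.tsv")
  ev <- if (file.exists(ev_path)) {
    readr::read_tsv(ev_path, show_col_types = FALSE,
                    col_types = readr::cols(chrom = "c", type = "c", seq = "c",
                                            strand = "c",
                                            .default = readr::col_integer())) |>
      mutate(pos = .data$pos - 1L)
  } else {
    empty_indel_events()
  }
  n_sscs <- NA_integer_
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    n_sscs <- jsonlite::read_json(meta_path)$n_sscs
  }
  new_pileup(tbl[, c(PILEUP_TSV_COLS[1:15], "cov_f", "cov_r", "coverage")],
             as_tibble(ev), n_sscs)
}
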