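#' Adapter and tag layout specification
#'
#' Describes where the molecular tag sits in a raw read and which residual
#' duplex-adapter sequence may trail the insert. The default layout is a
#' single contiguous tag at the 5' end of the read; the tag length is a
#' configuration knob, 10 nt by default (long enough that random tag
#' collisions at panel-scale molecule counts are rare).
#'
#' @param tag_length tag length in nucleotides (>= 1)
#' @param duplex_adapter_seq residual adapter sequence that may follow the
#'   insert at the read 3' end (alphabet ACGT)
#' @param max_adapter_mismatches mismatches tolerated when matching the
#'   adapter suffix
#' @param min_adapter_overlap shortest adapter prefix considered a 3' match
#'   when the read ends inside the adapter
#' @return an `adapter_spec` list
#' @export
adapter_spec <- function(tag_length = 10L,
                         duplex_adapter_seq = "ATCACCGACTGCCC",
                         max_adapter_mismatches = 1L,
                         min_adapter_overlap = 6L) {
  tag_length <- as.integer(tag_length)
  assert_that(tag_length >= 1L, "tag_length must be >= 1")
  assert_that(grepl("^[ACGT]+$", duplex_adapter_seq),
              "duplex_adapter_seq must be over {A,C,G,T}")
  structure(list(tag_length = tag_length,
                 duplex_adapter_seq = toupper(duplex_adapter_seq),
                 max_adapter_mismatches = as.integer(max_adapter_mismatches),
                 min_adapter_overlap = as.integer(min_adapter_overlap)),
            class = "adapter_spec")
}

# Offset (1-based, within insert+suffix string) at which the adapter starts,
# or NA. Scans left to right so read-through junk after the adapter is also
# removed; a trailing partial adapter (down to min_adapter_overlap bases)
# counts as a match.
adapter_start <- function(seq, spec) {
  n <- nchar(seq)
  a <- spec$duplex_adapter_seq
  la <- nchar(a)
  if (n < spec$min_adapter_overlap) return(NA_integer_)
  ai <- utf8ToInt(a)
  si <- utf8ToInt(seq)
  for (j in seq_len(n - spec$min_adapter_overlap + 1L)) {
    len <- min(la, n - j + 1L)
    mm <- sum(si[j:(j + len - 1L)] != ai[seq_len(len)])
    if (mm <= spec$max_adapter_mismatches) return(j)
  }
  NA_integer_
}

#' Extract molecular tags and trim residual adapter
#'
#' Splits each raw aligned read into its 5' molecular tag and the insert,
#' removing any 3' suffix matching the duplex adapter within the allowed
#' mismatch budget. Reads shorter than `tag_length + 1` are rejected with
#' reason `"too_short"`; tags containing more than one `N` are rejected with
#' reason `"ambiguous_tag"`. Strand is copied from the alignment orientation.
#'
#' @param raw_reads tibble of raw aligned reads with columns `read_id`,
#'   `chrom`, `start` (0-based), `strand` (`"+"`/`"-"`), `bases`, `quals`
#'   (phred+33 string), and optionally `cigar`
#' @param spec an [adapter_spec()]
#' @return tibble of tagged reads (`read_id`, `tag`, `chrom`, `start`,
#'   `strand`, `cigar`, `bases`, `quals`) with attribute `"rejects"`: a
#'   tibble of `read_id`, `reason` for dropped reads
#' @export
extract_tag <- function(raw_reads, spec = adapter_spec()) {
  stopifnot(is.data.frame(raw_reads))
  if (!"cigar" %in% names(raw_reads)) raw_reads$cigar <- NA_character_
  L <- spec$tag_length
  len <- nchar(raw_reads$bases)

  too_short <- len < L + 1L
  tag <- ifelse(too_short, NA_character_, substr(raw_reads$bases, 1L, L))
  n_in_tag <- stringr::str_count(tag, "N")
  ambiguous <- !too_short & n_in_tag > 1L

  keep <- !too_short & !ambiguous
  rejects <- tibble(
    read_id = raw_reads$read_id[!keep],
    reason = ifelse(too_short[!keep], "too_short", "ambiguous_tag")
  )

  kept <- raw_reads[keep, , drop = FALSE]
  insert <- substr(kept$bases, L + 1L, nchar(kept$bases))
  iquals <- substr(kept$quals, L + 1L, nchar(kept$quals))
  cut <- vapply(insert, adapter_start, 1L, spec = spec, USE.NAMES = FALSE)
  has_ad <- !is.na(cut)
  insert[has_ad] <- substr(insert[has_ad], 1L, cut[has_ad] - 1L)
  iquals[has_ad] <- substr(iquals[has_ad], 1L, cut[has_ad] - 1L)

  out <- tibble(
    read_id = kept$read_id,
    tag = substr(kept$bases, 1L, L),
    chrom = kept$chrom,
    start = as.integer(kept$start),
    strand = kept$strand,
    cigar = ifelse(is.na(kept$cigar), paste0(nchar(insert), "M"), kept$cigar),
    bases = insert,
    quals = iquals
  )
  attr(out, "rejects") <- rejects
  out
}

TSV_COLS <- c("read_id", "tag", "chrom", "start", "strand", "cigar", "bases", "quals")

#' Read tagged reads from the tabular dialect
#'
#' The dialect is a TSV with header columns `read_id`, `tag`, `chrom`,
#' `start` (0-based), `strand`, `cigar`, `bases`, `quals`. Malformed records
#' (wrong field count, tag not matching `[ACGTN]+`, base/qual length
#' mismatch) are counted, reported via a message, and skipped.
#'
#' @param path TSV file path
#' @return tibble of tagged reads, attribute `"n_skipped"` giving the number
#'   of malformed records dropped
#' @export
read_tagged_reads <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) {
    out <- tibble(read_id = character(), tag = character(), chrom = character(),
                  start = integer(), strand = character(), cigar = character(),
                  bases = character(), quals = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  assert_that(identical(header, TSV_COLS), "untagged_input: unexpected header")
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf == length(TSV_COLS)
  mat <- do.call(rbind, fields[ok])
  if (is.null(mat)) mat <- matrix(character(), ncol = length(TSV_COLS))
  out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(out) <- TSV_COLS
  out$start <- suppressWarnings(as.integer(out$start))
  good <- !is.na(out$start) &
    grepl("^[ACGTN]+$", out$tag) &
    nchar(out$bases) == nchar(out$quals) &
    out$strand %in% c("+", "-")
  n_skipped <- sum(!ok) + sum(!good)
  if (n_skipped > 0L) {
    inform(sprintf("read_tagged_reads: skipped %d malformed record(s) in %s",
                   n_skipped, path))
  }
  out <- out[good, , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write tagged reads in the tabular dialect
#' @param reads tibble of tagged reads
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_tagged_reads <- function(reads, path) {
  readr::write_tsv(reads[, TSV_COLS], path)
  invisible(path)
}

#' Read tagged reads from SAM/BAM
#'
#' The molecular tag is taken from an auxiliary string field (default `RX`,
#' the SAM-standard UMI field). SAM text input is converted on the fly.
#' Unmapped records are dropped and counted.
#'
#' @param path SAM or BAM file
#' @param tag_field two-letter auxiliary field holding the tag
#' @return tibble of tagged reads (same shape as [read_tagged_reads()])
#' @export
read_tagged_sam <- function(path, tag_field = "RX") {
  assert_that(file.exists(path), paste0("no such file: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq", "qual"),
    tag = tag_field)
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  tags <- res$tag[[tag_field]]
  if (is.null(tags)) abort("untagged_input: tag field missing from SAM/BAM")
  mapped <- !is.na(res$pos)
  n_skipped <- sum(!mapped)
  if (n_skipped > 0L)
    inform(sprintf("read_tagged_sam: dropped %d unmapped record(s)", n_skipped))
  out <- tibble(
    read_id = res$qname[mapped],
    tag = tags[mapped],
    chrom = as.character(res$rname)[mapped],
    start = res$pos[mapped] - 1L,
    strand = as.character(res$strand)[mapped],
    cigar = res$cigar[mapped],
    bases = as.character(res$seq)[mapped],
    quals = as.character(res$qual)[mapped]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Restrict tagged reads to a capture panel
#'
#' Reads whose aligned span does not overlap any panel interval are dropped
#' (off-target), with the dropped count attached as attribute
#' `"n_off_panel"`.
#'
#' @param reads tibble of tagged reads
#' @param panel tibble `chrom`, `start`, `end` (0-based half-open)
#' @return on-panel subset of `reads`
#' @export
filter_on_panel <- function(reads, panel) {
  if (nrow(reads) == 0L) {
    attr(reads, "n_off_panel") <- 0L
    return(reads)
  }
  span <- cigar_ref_span(reads$cigar)
  end <- reads$start + span
  on <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(panel))) {
    on <- on | (reads$chrom == panel$chrom[i] &
                  reads$start < panel$end[i] & end > panel$start[i])
  }
  out <- reads[on, , drop = FALSE]
  attr(out, "n_off_panel") <- sum(!on)
  out
}
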