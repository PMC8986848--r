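#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows count n n_distinct row_number
#'   distinct rename pull across first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median pbinom qbeta rbinom rgeom rpois runif setNames cor sd
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# All genomic coordinates are 0-based half-open internally; conversion to
# 1-based happens only at VCF / TSV emission and BED import.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

#' Normalise a reference to a named character vector of contig sequences
#' @param reference a named character vector, a `Biostrings::DNAStringSet`,
#'   or a path to a FASTA file
#' @return named character vector (one element per contig, uppercase)
#' @export
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    return(read_reference(reference))
  }
  if (methods::is(reference, "DNAStringSet")) {
    return(setNames(toupper(as.character(reference)), names(reference)))
  }
  if (is.character(reference)) {
    assert_that(!is.null(names(reference)), "reference must have contig names")
    return(toupper(reference))
  }
  abort("unsupported reference type")
}

#' Read a FASTA reference
#' @param path FASTA file path
#' @return named character vector of contig sequences
#' @export
read_reference <- function(path) {
  as_reference(Biostrings::readDNAStringSet(path))
}

#' Write a reference to FASTA
#' @param reference named character vector or DNAStringSet
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_reference <- function(reference, path) {
  reference <- as_reference(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read a BED interval file
#'
#' Intervals are returned 0-based half-open (BED native).
#'
#' @param path BED file (3 columns minimum)
#' @return tibble with columns `chrom`, `start`, `end`
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end   = BiocGenerics::end(gr)
  )
}

#' Write intervals to BED
#' @param panel tibble with `chrom`, `start`, `end` (0-based half-open)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(panel, path) {
  readr::write_tsv(panel[, c("chrom", "start", "end")], path, col_names = FALSE)
  invisible(path)
}

# Expand a panel to its individual positions (0-based)
panel_positions <- function(panel) {
  if (nrow(panel) == 0L) return(tibble(chrom = character(), pos = integer()))
  tibble(
    chrom = rep(panel$chrom, panel$end - panel$start),
    pos = unlist(purrr::map2(panel$start, panel$end, ~ seq.int(.x, .y - 1L)),
                 use.names = FALSE)
  )
}

# Logical membership of (chrom, pos) in a position mask (tibble chrom/pos),
# possibly empty or NULL
in_position_set <- function(chrom, pos, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(pos)))
  key <- paste(chrom, pos)
  key %in% paste(mask$chrom, mask$pos)
}

#' Read a SNP-position mask from BED
#' @param path BED file of masked positions
#' @return tibble with `chrom`, `pos` (0-based), one row per masked position
#' @export
read_snp_mask <- function(path) {
  panel_positions(read_bed(path))
}

## ---- CIGAR ------------------------------------------------------------

# Parse CIGAR strings into a list of list(len = int, op = chr).
# Plain vectors, no tibbles: this sits on the consensus hot path.
parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  lapply(m, function(x) {
    list(len = as.integer(substr(x, 1L, nchar(x) - 1L)),
         op = substr(x, nchar(x), nchar(x)))
  })
}

# Reference span consumed by a CIGAR (M/D/N/=/X ops)
cigar_ref_span <- function(cigar) {
  vapply(parse_cigar(cigar), function(o) {
    sum(o$len[o$op %in% c("M", "D", "N", "=", "X")])
  }, 1L)
}

# Expand one read's alignment into per-reference-position alleles.
# Returns list(pos = int vector (0-based), allele = char vector over
# {A,C,G,T,N,-}, ins_pos = int, ins_seq = chr) where insertion position is
# the reference position of the base preceding the inserted sequence.
# Plain vectors (no tibbles): this sits on the consensus hot path.
expand_alignment <- function(bases, start, cigar) {
  ops <- parse_cigar(cigar)[[1]]
  rp <- start       # next reference position
  qp <- 1L          # next query offset (1-based within bases)
  pos <- integer(0); allele <- character(0)
  ins_pos <- integer(0); ins_seq <- character(0)
  for (i in seq_along(ops$len)) {
    len <- ops$len[i]; op <- ops$op[i]
    if (len == 0L) next
    if (op %in% c("M", "=", "X")) {
      pos <- c(pos, rp + 0:(len - 1L))
      allele <- c(allele, strsplit(substr(bases, qp, qp + len - 1L), "", fixed = TRUE)[[1]])
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") {
      ins_pos <- c(ins_pos, rp - 1L)
      ins_seq <- c(ins_seq, substr(bases, qp, qp + len - 1L))
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      pos <- c(pos, rp + 0:(len - 1L))
      allele <- c(allele, rep("-", len))
      rp <- rp + len
    } else if (op %in% c("S", "H", "P")) {
      if (op == "S") qp <- qp + len
    }
  }
  list(pos = pos, allele = allele, ins_pos = ins_pos, ins_seq = ins_seq)
}

## ---- small helpers ----------------------------------------------------

# Hamming distance between equal-length strings (vectorised over y)
hamming_dist <- function(x, y) {
  xi <- utf8ToInt(x)
  vapply(y, function(s) sum(utf8ToInt(s) != xi), 1L, USE.NAMES = FALSE)
}

# Random DNA strings: n strings of length len (uses current RNG stream)
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  mat <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# Substring of a contig, 0-based half-open
ref_slice <- function(reference, chrom, start, end) {
  substr(reference[[chrom]], start + 1L, end)
}

# Deterministic full-precision number formatting for text round-trips
num_chr <- function(x) sprintf("%.17g", x)

pkg_version <- function() {
  as.character(utils::packageVersion("plasmacall"))
}
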