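# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-implementations kept separate from the package's code paths.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

tiny_reference <- function(len = 120L, chrom = "chrT", seed = 404L) {
  simulate_reference(len, chrom, seed = seed)
}

tiny_panel <- function(reference, margin = 10L) {
  tibble(chrom = names(reference)[1], start = margin,
         end = nchar(reference[[1]]) - margin)
}

# Build a tagged-read tibble from parallel vectors with sensible defaults
make_reads <- function(bases, tag = "ACGTACGTAC", chrom = "chrT", start = 0L,
                       strand = "+", cigar = NULL, read_id = NULL) {
  n <- length(bases)
  if (is.null(cigar)) cigar <- paste0(nchar(bases), "M")
  tibble(
    read_id = read_id %||% paste0("r", seq_len(n)),
    tag = rep_len(tag, n), chrom = rep_len(chrom, n),
    start = as.integer(rep_len(start, n)), strand = rep_len(strand, n),
    cigar = rep_len(cigar, n), bases = bases,
    quals = strrep("I", nchar(bases))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A pileup whose coverage comes from size-1 families of single-base reads:
# n_ref reference reads plus n_alt alt reads at one position, half of each
# on either strand. Returns the sscs_pileup.
one_position_pileup <- function(reference, panel, pos, alt, n_ref, n_alt) {
  ref_base <- substr(reference[[1]], pos + 1L, pos + 1L)
  n <- n_ref + n_alt
  strands <- rep(c("+", "-"), length.out = n)
  reads <- make_reads(
    bases = c(rep(ref_base, n_ref), rep(alt, n_alt)),
    tag = random_tags(n), chrom = names(reference)[1], start = pos,
    strand = strands
  )
  build_pileup(collapse_families(reads, consensus_config(tag_merge_hamming = 0L)),
               panel, reference)
}

random_dna_strings <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

random_tags <- function(n, len = 10L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

## ---- independent oracles ---------------------------------------------

# Brute-force per-position consensus voter, independent of the package's
# expansion machinery: walks each member's CIGAR with scalar string ops and
# tallies votes with table().
oracle_collapse <- function(bases, start, cigar, thr = 0.7) {
  expand1 <- function(b, s, cg) {
    nums <- as.integer(strsplit(gsub("[A-Z]", " ", cg), " +")[[1]])
    ops <- strsplit(gsub("[0-9]", "", cg), "")[[1]]
    out <- list()
    rp <- s; qp <- 1L
    for (i in seq_along(ops)) {
      L <- nums[i]
      if (L == 0L) next
      if (ops[i] == "M") {
        for (j in seq_len(L)) {
          out[[length(out) + 1L]] <- list(pos = rp, al = substr(b, qp, qp))
          rp <- rp + 1L; qp <- qp + 1L
        }
      } else if (ops[i] == "D") {
        for (j in seq_len(L)) {
          out[[length(out) + 1L]] <- list(pos = rp, al = "-")
          rp <- rp + 1L
        }
      } else if (ops[i] == "I") {
        qp <- qp + L
      } else if (ops[i] == "S") {
        qp <- qp + L
      }
    }
    out
  }
  votes <- list()
  for (i in seq_along(bases)) {
    for (v in expand1(bases[i], start[i], cigar[i])) {
      key <- as.character(v$pos)
      votes[[key]] <- c(votes[[key]], v$al)
    }
  }
  positions <- sort(as.integer(names(votes)))
  cons <- vapply(positions, function(p) {
    vs <- votes[[as.character(p)]]
    tb <- table(vs)
    winner <- names(tb)[which.max(tb)]
    if (max(tb) / length(vs) > thr + 1e-12) winner else "N"
  }, "")
  list(start = positions[1], bases = paste(cons, collapse = ""))
}

# Exhaustive binomial upper-tail via explicit pmf summation on log scale
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# Brute-force background accumulation over pileups: per position and alt
# base, sum alt counts and coverages with plain loops.
oracle_background <- function(pileups) {
  out <- list()
  for (pl in pileups) {
    tb <- as.data.frame(pl)
    for (i in seq_len(nrow(tb))) {
      for (b in c("A", "C", "G", "T")) {
        if (b == tb$ref[i]) next
        key <- paste(tb$chrom[i], tb$pos[i], b)
        k <- tb[[paste0(b, "_f")]][i] + tb[[paste0(b, "_r")]][i]
        prev <- out[[key]] %||% c(0L, 0L)
        out[[key]] <- c(prev[1] + k, prev[2] + tb$coverage[i])
      }
    }
  }
  out
}
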