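# Consensus collapsing: read families keyed by (tag, alignment start,
# strand), directional merging of tag-error neighbours, and the strict
# majority vote that turns a family into a single-strand consensus sequence.

#' Consensus configuration
#'
#' @param majority_threshold fraction a consensus allele must strictly
#'   exceed among covering family members (default 0.70; a position at
#'   exactly 70.0% support yields `N`)
#' @param min_family_size families below this size are rejected (default 1,
#'   i.e. no minimum: a single read represents one strand)
#' @param tag_merge_hamming merge a family into a strictly larger family at
#'   the same (chrom, start, strand) whose tag is within this Hamming
#'   distance (0 disables merging)
#' @return a `consensus_config` list
#' @export
consensus_config <- function(majority_threshold = 0.70,
                             min_family_size = 1L,
                             tag_merge_hamming = 1L) {
  assert_that(majority_threshold >= 0.5 && majority_threshold < 1,
              "majority_threshold must be in [0.5, 1)")
  assert_that(min_family_size >= 1L, "min_family_size must be >= 1")
  structure(list(majority_threshold = majority_threshold,
                 min_family_size = as.integer(min_family_size),
                 tag_merge_hamming = as.integer(tag_merge_hamming)),
            class = "consensus_config")
}

#' Group tagged reads into families
#'
#' A family is the set of reads sharing one (tag, chrom, alignment start,
#' strand) key — the unit that represents a single original cfDNA strand.
#' Families partition the input: every read belongs to exactly one family.
#'
#' @param reads tagged-read tibble
#' @return tibble with one row per family: `family_id`, `tag`, `chrom`,
#'   `start`, `strand`, `size`, and `members`, a list column of row indices
#'   into `reads`
#' @export
build_families <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(family_id = integer(), tag = character(),
                  chrom = character(), start = integer(), strand = character(),
                  size = integer(), members = list()))
  }
  key <- paste(reads$tag, reads$chrom, reads$start, reads$strand, sep = "\r")
  f <- match(key, unique(key))
  members <- split(seq_len(nrow(reads)), f)
  idx <- vapply(members, `[[`, 1L, 1L)
  tibble(
    family_id = seq_along(members),
    tag = reads$tag[idx],
    chrom = reads$chrom[idx],
    start = as.integer(reads$start[idx]),
    strand = reads$strand[idx],
    size = unname(lengths(members)),
    members = unname(members)
  )
}

#' Merge tag-sequencing-error neighbour families
#'
#' Within one (chrom, start, strand) locus, a family whose tag lies within
#' `max_hamming` of a strictly larger family's tag is absorbed into that
#' family (directional, largest first; ties among candidate absorbers broken
#' lexicographically by tag). This removes spurious extra families created
#' by sequencing errors inside the molecular tag; two equal-sized neighbours
#' are never merged.
#'
#' @param families output of [build_families()]
#' @param max_hamming maximum tag Hamming distance absorbed
#' @return families tibble of the same shape, after absorption
#' @export
merge_tag_neighbors <- function(families, max_hamming = 1L) {
  if (max_hamming <= 0L || nrow(families) < 2L) return(families)
  locus <- paste(families$chrom, families$start, families$strand, sep = "\r")
  parent <- seq_len(nrow(families))
  for (grp in split(seq_len(nrow(families)), locus)) {
    if (length(grp) < 2L) next
    ord <- grp[order(-families$size[grp], families$tag[grp])]
    for (i in seq_along(ord)[-1L]) {
      me <- ord[i]
      bigger <- ord[seq_len(i - 1L)]
      bigger <- bigger[families$size[bigger] > families$size[me]]
      if (length(bigger) == 0L) next
      d <- hamming_dist(families$tag[me], families$tag[bigger])
      hit <- which(d <= max_hamming)
      if (length(hit) > 0L) parent[me] <- bigger[hit[1L]]
    }
  }
  # resolve absorption chains (parents always have strictly larger original
  # size, so chains terminate)
  repeat {
    nxt <- parent[parent]
    if (identical(nxt, parent)) break
    parent <- nxt
  }
  if (all(parent == seq_along(parent))) return(families)
  grp <- split(seq_len(nrow(families)), parent)
  roots <- as.integer(names(grp))
  merged <- tibble(
    family_id = seq_along(roots),
    tag = families$tag[roots],
    chrom = families$chrom[roots],
    start = families$start[roots],
    strand = families$strand[roots],
    size = unname(vapply(grp, function(g) sum(families$size[g]), 1L)),
    members = lapply(grp, function(g) {
      unlist(families$members[g], use.names = FALSE)
    })
  )
  merged$members <- unname(merged$members)
  merged
}

# Vote a family into a consensus. Takes member vectors; all members share
# the same alignment start. Returns list(bases, ins = tibble(pos, seq)).
# `bases` spans min..max covered reference position, with N where no allele
# strictly exceeds the threshold among covering members and "-" where the
# consensus is a deletion.
vote_family <- function(bases, start, cigar, thr) {
  n_mem <- length(bases)
  exps <- lapply(seq_len(n_mem),
                 function(i) expand_alignment(bases[i], start[i], cigar[i]))
  pos <- unlist(lapply(exps, `[[`, "pos"), use.names = FALSE)
  allele <- unlist(lapply(exps, `[[`, "allele"), use.names = FALSE)
  span0 <- min(pos); span1 <- max(pos)
  width <- span1 - span0 + 1L
  rel <- pos - span0 + 1L
  denom <- tabulate(rel, nbins = width)

  cons <- rep("N", width)
  alleles <- c(DNA_BASES, "-", "N")
  aidx <- match(allele, alleles)
  code <- (rel - 1L) * 6L + aidx
  cnt <- tabulate(code, nbins = width * 6L)
  cnt <- matrix(cnt, nrow = width, ncol = 6L, byrow = TRUE)
  best <- max.col(cnt[, 1:5, drop = FALSE], ties.method = "first")
  bestn <- cnt[cbind(seq_len(width), best)]
  # strict inequality, guarded against floating-point ties at the boundary
  # (an exact 70.0% fraction must never win)
  win <- denom > 0L & bestn / pmax(denom, 1L) - thr > 1e-9
  cons[win] <- alleles[best[win]]

  ins_pos <- unlist(lapply(exps, `[[`, "ins_pos"), use.names = FALSE)
  ins_seq <- unlist(lapply(exps, `[[`, "ins_seq"), use.names = FALSE)
  ins_out <- tibble(pos = integer(), seq = character())
  if (length(ins_pos) > 0L) {
    ok <- ins_pos >= span0
    ins_pos <- ins_pos[ok]; ins_seq <- ins_seq[ok]
    if (length(ins_pos) > 0L) {
      key <- paste(ins_pos, ins_seq)
      u_idx <- which(!duplicated(key))
      k <- tabulate(match(key, key[u_idx]), nbins = length(u_idx))
      upos <- ins_pos[u_idx]; useq <- ins_seq[u_idx]
      dnm <- denom[upos - span0 + 1L]
      keep <- k / dnm - thr > 1e-9
      ins_out <- tibble(pos = upos[keep], seq = useq[keep])
    }
  }
  list(start = span0, bases = paste(cons, collapse = ""), ins = ins_out)
}

# Indel events encoded in one consensus string: deletions as "-" runs
del_events_from_bases <- function(bases, start) {
  r <- rle(strsplit(bases, "", fixed = TRUE)[[1]] == "-")
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- r$values
  tibble(pos = start + begins[keep] - 1L, length = r$lengths[keep])
}

#' Collapse a single read family into a consensus record
#'
#' At each reference position, the consensus allele is the allele carried by
#' a fraction of covering members strictly greater than
#' `majority_threshold`; otherwise the position is `N`. Deletions and
#' insertions follow the same vote (a deleted position is marked `-` in the
#' consensus string and reported in `indels`). Families smaller than
#' `min_family_size` return a rejection.
#'
#' @param family tibble of the family's member reads (rows of a tagged-read
#'   tibble sharing one key)
#' @param cfg a [consensus_config()]
#' @return list with `key` (tag, chrom, start, strand), `bases`,
#'   `family_size` and `indels` (tibble `pos`, `type`, `seq`, `length`);
#'   or, for undersized families, `list(rejected = TRUE, reason =
#'   "family_too_small")`
#' @export
collapse_family <- function(family, cfg = consensus_config()) {
  assert_that(nrow(family) >= 1L, "family must have at least one member")
  if (nrow(family) < cfg$min_family_size) {
    return(list(rejected = TRUE, reason = "family_too_small"))
  }
  v <- vote_family(family$bases, family$start, family$cigar,
                   cfg$majority_threshold)
  dels <- del_events_from_bases(v$bases, v$start)
  indels <- bind_rows(
    if (nrow(dels) > 0L)
      mutate(dels, type = "del", seq = strrep("-", .data$length)),
    if (nrow(v$ins) > 0L)
      mutate(v$ins, type = "ins", length = nchar(.data$seq))
  )
  if (is.null(indels) || nrow(indels) == 0L) {
    indels <- tibble(pos = integer(), type = character(),
                     seq = character(), length = integer())
  }
  list(
    key = list(tag = family$tag[1], chrom = family$chrom[1],
               start = v$start, strand = family$strand[1]),
    bases = v$bases,
    family_size = nrow(family),
    indels = indels[, c("pos", "type", "seq", "length")]
  )
}

#' Collapse all families of a sample into consensus records
#'
#' Builds families, optionally merges tag-error neighbours, and collapses
#' each family under the strict majority vote. Families whose members agree
#' exactly (identical bases and CIGAR — the vast majority at realistic
#' error rates) are collapsed by identity; disagreeing families go through
#' the per-position voter.
#'
#' @param reads tagged-read tibble
#' @param cfg a [consensus_config()]
#' @param families optional precomputed [build_families()] output (tag
#'   merging is then the caller's responsibility)
#' @return `sscs_records` tibble: `tag`, `chrom`, `start`, `strand`,
#'   `family_size`, `bases` (alphabet ACGTN-); attributes `"insertions"`
#'   (tibble `chrom`, `pos`, `strand`, `seq` of consensus insertion events)
#'   and `"n_rejected"` (families below `min_family_size`)
#' @export
collapse_families <- function(reads, cfg = consensus_config(),
                              families = NULL) {
  if (is.null(families)) {
    families <- build_families(reads)
    if (cfg$tag_merge_hamming > 0L) {
      families <- merge_tag_neighbors(families, cfg$tag_merge_hamming)
    }
  }
  n_rejected <- sum(families$size < cfg$min_family_size)
  families <- families[families$size >= cfg$min_family_size, , drop = FALSE]

  if (nrow(families) == 0L) {
    out <- tibble(tag = character(), chrom = character(), start = integer(),
                  strand = character(), family_size = integer(),
                  bases = character())
    attr(out, "insertions") <- tibble(chrom = character(), pos = integer(),
                                      strand = character(), seq = character())
    attr(out, "n_rejected") <- n_rejected
    class(out) <- c("sscs_records", class(out))
    return(out)
  }

  first_idx <- vapply(families$members, `[[`, 1L, 1L)
  agree <- vapply(families$members, function(m) {
    length(unique(reads$bases[m])) == 1L && length(unique(reads$cigar[m])) == 1L
  }, TRUE)
  pure_m <- grepl("^\\d+M$", reads$cigar[first_idx])

  cons_start <- as.integer(reads$start[first_idx])
  cons_bases <- character(nrow(families))
  ins_list <- vector("list", nrow(families))

  # identity fast path: agreeing, gapless families
  fast <- agree & pure_m
  cons_bases[fast] <- reads$bases[first_idx[fast]]

  # agreeing families with an indel CIGAR: expand the representative once
  for (i in which(agree & !pure_m)) {
    e <- expand_alignment(reads$bases[first_idx[i]], cons_start[i],
                          reads$cigar[first_idx[i]])
    cons_bases[i] <- paste(e$allele, collapse = "")
    if (length(e$ins_pos) > 0L) {
      ins_list[[i]] <- tibble(pos = e$ins_pos, seq = e$ins_seq)
    }
  }

  # general path: per-position vote
  for (i in which(!agree)) {
    m <- families$members[[i]]
    v <- vote_family(reads$bases[m], reads$start[m], reads$cigar[m],
                     cfg$majority_threshold)
    cons_start[i] <- v$start
    cons_bases[i] <- v$bases
    if (nrow(v$ins) > 0L) ins_list[[i]] <- v$ins
  }

  out <- tibble(
    tag = families$tag, chrom = families$chrom, start = cons_start,
    strand = families$strand, family_size = families$size,
    bases = cons_bases
  )
  has_ins <- !vapply(ins_list, is.null, TRUE)
  insertions <- if (any(has_ins)) {
    bind_rows(purrr::map(which(has_ins), function(i) {
      mutate(ins_list[[i]], chrom = out$chrom[i], strand = out$strand[i])
    }))[, c("chrom", "pos", "strand", "seq")]
  } else {
    tibble(chrom = character(), pos = integer(), strand = character(),
           seq = character())
  }
  attr(out, "insertions") <- insertions
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("sscs_records", class(out))
  out
}

#' Write consensus records to TSV
#' @param sscs an `sscs_records` tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sscs <- function(sscs, path) {
  readr::write_tsv(as_tibble(sscs), path)
  ins <- attr(sscs, "insertions")
  if (!is.null(ins) && nrow(ins) > 0L) {
    readr::write_tsv(ins, paste0(path, ".insertions.tsv"))
  }
  invisible(path)
}
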