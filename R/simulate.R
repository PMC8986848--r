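# Synthetic tagged-read generator: emits panel-restricted, aligned,
# tag-carrying reads with a truth manifest, emulating a tag-based capture
# library: molecules drawn from input mass and recovery, read families with
# a configurable size distribution, per-base substitution/indel errors, tag
# sequencing errors, and spike-in variants at set VAFs.

NG_PER_HAPLOID_GENOME <- 0.0033  # ng of DNA per haploid human genome

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults emulate the validation design the package targets: ~160 bp
#' cfDNA-like fragments (+/- 20 bp uniform jitter), 50 ng input at 22.1%
#' molecular recovery, strand-symmetric molecules, 10 nt molecular tags
#' drawn uniformly at random, and read families distributed as a
#' zero-truncated Poisson around the configured mean.
#'
#' @param reference named character vector (or DNAStringSet / FASTA path)
#' @param panel tibble `chrom`, `start`, `end` (0-based half-open)
#' @param seed integer seed, or `NULL` to use the current RNG stream
#' @param input_mass_ng cfDNA input mass in ng; molecules are
#'   `2 * mass / 0.0033` single strands
#' @param recovery fraction of input molecules yielding at least one read
#' @param family_size_mean mean reads per recovered molecule
#' @param family_size_dist `"ztpois"` (zero-truncated Poisson) or
#'   `"geometric"` (on 1, 2, ...)
#' @param fragment_length median fragment length (bp)
#' @param fragment_jitter uniform half-width of fragment-length jitter (bp)
#' @param raw_substitution_rate per-base substitution error rate in reads
#' @param raw_indel_rate per-base indel error rate in reads (at most one
#'   indel is injected per read)
#' @param tag_error_rate per-base substitution error rate within the tag
#' @param tag_length tag length (nt)
#' @param spike_ins tibble `chrom`, `pos` (0-based), `ref`, `alt`, `vaf` of
#'   spike-in SNVs, or `NULL`
#' @return a `simulation_config` list
#' @export
simulation_config <- function(reference, panel,
                              seed = NULL,
                              input_mass_ng = 50,
                              recovery = 0.221,
                              family_size_mean = 3,
                              family_size_dist = c("ztpois", "geometric"),
                              fragment_length = 160L,
                              fragment_jitter = 20L,
                              raw_substitution_rate = 1e-3,
                              raw_indel_rate = 1e-4,
                              tag_error_rate = 1e-3,
                              tag_length = 10L,
                              spike_ins = NULL) {
  family_size_dist <- match.arg(family_size_dist)
  reference <- as_reference(reference)
  rates <- c(recovery, raw_substitution_rate, raw_indel_rate, tag_error_rate)
  assert_that(all(rates >= 0 & rates <= 1), "rates must be in [0, 1]")
  assert_that(input_mass_ng > 0, "input_mass_ng must be positive")
  if (!is.null(spike_ins) && nrow(spike_ins) > 0) {
    pp <- panel_positions(panel)
    ok <- in_position_set(spike_ins$chrom, spike_ins$pos, pp)
    assert_that(all(ok), "spike-in position outside the panel")
    assert_that(all(spike_ins$vaf >= 0 & spike_ins$vaf <= 1),
                "spike-in VAF must be in [0, 1]")
  }
  structure(list(reference = reference, panel = panel, seed = seed,
                 input_mass_ng = input_mass_ng, recovery = recovery,
                 family_size_mean = family_size_mean,
                 family_size_dist = family_size_dist,
                 fragment_length = as.integer(fragment_length),
                 fragment_jitter = as.integer(fragment_jitter),
                 raw_substitution_rate = raw_substitution_rate,
                 raw_indel_rate = raw_indel_rate,
                 tag_error_rate = tag_error_rate,
                 tag_length = as.integer(tag_length),
                 spike_ins = spike_ins),
            class = "simulation_config")
}

#' Generate a random reference contig
#' @param length contig length (bp)
#' @param chrom contig name
#' @param seed optional seed
#' @return named character vector of length 1
#' @export
simulate_reference <- function(length = 1000L, chrom = "sim1", seed = NULL) {
  with_seed_local(seed, setNames(random_dna(1L, length), chrom))
}

#' Pick evenly spaced spike-in SNVs across a panel
#'
#' Positions are spread evenly over the panel; the alternative allele is the
#' reference base rotated one step in A>C>G>T>A order (deterministic).
#'
#' @param reference reference (any form accepted by [as_reference()])
#' @param panel panel tibble
#' @param n number of variants
#' @param vaf nominal VAF assigned to every variant
#' @return spike-in tibble for [simulation_config()]
#' @export
pick_spike_variants <- function(reference, panel, n = 6L, vaf = 0.005) {
  reference <- as_reference(reference)
  pp <- panel_positions(panel)
  idx <- round(seq(1, nrow(pp), length.out = n + 2L))[2:(n + 1L)]
  pos <- pp$pos[idx]; chrom <- pp$chrom[idx]
  ref <- substr(reference[chrom], pos + 1L, pos + 1L)
  rot <- setNames(c("C", "G", "T", "A"), DNA_BASES)
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
         alt = unname(rot[ref]), vaf = vaf)
}

# Zero-truncated Poisson sampler with a given mean (>= 1)
rztpois <- function(n, mean) {
  assert_that(mean > 1, "zero-truncated Poisson needs mean > 1")
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                           c(1e-8, mean * 2 + 10))$root
  out <- rpois(n, lambda)
  while (any(out == 0L)) {
    z <- out == 0L
    out[z] <- rpois(sum(z), lambda)
  }
  out
}

rfamily_sizes <- function(n, cfg) {
  if (n == 0L) return(integer(0))
  if (cfg$family_size_dist == "geometric") {
    1L + rgeom(n, 1 / cfg$family_size_mean)
  } else {
    rztpois(n, cfg$family_size_mean)
  }
}

#' Simulate one tagged-read sample with its truth manifest
#'
#' Molecule counts are driven by input mass (2 single strands per genome
#' equivalent at 0.0033 ng per haploid genome) thinned by the recovery
#' fraction. Each molecule receives a random tag, a fragment locus
#' overlapping the panel, and a strand; spike-in alternative alleles are
#' allocated binomially at the nominal VAF among molecules covering the
#' position. Reads per molecule follow the configured family-size
#' distribution; substitution, indel and tag errors are injected
#' independently per base. Deterministic under a fixed seed.
#'
#' @param cfg a [simulation_config()]
#' @param seed overrides `cfg$seed` when given
#' @return list with `reads` (tagged-read tibble) and `truth` (manifest:
#'   `molecules`, `variants`, `reads` error bookkeeping, `seed`)
#' @export
simulate_sample <- function(cfg, seed = cfg$seed) {
  with_seed_local(seed, simulate_sample_impl(cfg, seed))
}

simulate_sample_impl <- function(cfg, seed) {
  ref <- cfg$reference
  panel <- cfg$panel
  n_input <- round(2 * cfg$input_mass_ng / NG_PER_HAPLOID_GENOME)
  n_mol <- rbinom(1L, n_input, cfg$recovery)

  if (n_mol == 0L) {
    return(list(reads = empty_reads(), truth = list(
      molecules = tibble(), variants = empty_variant_truth(cfg),
      reads = tibble(), n_input_molecules = n_input, seed = seed)))
  }

  frag_len <- cfg$fragment_length +
    sample.int(2L * cfg$fragment_jitter + 1L, n_mol, replace = TRUE) -
    cfg$fragment_jitter - 1L

  # interval chosen per molecule with probability proportional to the
  # number of admissible fragment placements overlapping it
  w <- (panel$end - panel$start) + cfg$fragment_length - 1
  iv <- sample.int(nrow(panel), n_mol, replace = TRUE, prob = w)
  lo <- pmax(panel$start[iv] - frag_len + 1L, 0L)
  hi <- pmin(panel$end[iv] - 1L,
             nchar(ref[panel$chrom[iv]]) - frag_len)
  start <- lo + floor(runif(n_mol) * (hi - lo + 1L))
  chrom <- panel$chrom[iv]
  strand <- sample(c("+", "-"), n_mol, replace = TRUE)
  tag <- random_dna(n_mol, cfg$tag_length)
  mol_seq <- substr(ref[chrom], start + 1L, start + frag_len)

  # spike-in allocation
  variants <- empty_variant_truth(cfg)
  spike_of_mol <- rep(NA_integer_, n_mol)
  si <- cfg$spike_ins
  if (!is.null(si) && nrow(si) > 0) {
    for (v in seq_len(nrow(si))) {
      cover <- chrom == si$chrom[v] & start <= si$pos[v] &
        start + frag_len > si$pos[v]
      is_alt <- cover & runif(n_mol) < si$vaf[v]
      off <- si$pos[v] - start + 1L
      idx <- which(is_alt)
      if (length(idx) > 0L) {
        substr(mol_seq[idx], off[idx], off[idx]) <- si$alt[v]
        spike_of_mol[idx] <- v
      }
      variants$n_covering[v] <- sum(cover)
      variants$n_alt[v] <- length(idx)
    }
    variants$realized_vaf <- ifelse(variants$n_covering > 0,
                                    variants$n_alt / variants$n_covering, 0)
  }

  # reads per molecule
  sizes <- rfamily_sizes(n_mol, cfg)
  mol_of_read <- rep.int(seq_len(n_mol), sizes)
  n_reads <- length(mol_of_read)
  bases <- mol_seq[mol_of_read]
  read_tag <- tag[mol_of_read]
  read_len <- frag_len[mol_of_read]
  cigar <- paste0(read_len, "M")

  # substitution errors (loop over the sparse error set; handles repeated
  # hits in one read correctly)
  B <- sum(read_len)
  cum <- c(0L, cumsum(read_len))
  n_sub <- rbinom(1L, B, cfg$raw_substitution_rate)
  sub_read <- integer(0)
  if (n_sub > 0L) {
    at <- sample.int(B, n_sub)
    sub_read <- findInterval(at - 0.5, cum)
    off <- at - cum[sub_read]
    for (i in seq_len(n_sub)) {
      r <- sub_read[i]
      cur <- substr(bases[r], off[i], off[i])
      substr(bases[r], off[i], off[i]) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }

  # indel errors: at most one per read
  n_ind <- rbinom(1L, B, cfg$raw_indel_rate)
  ind_read <- integer(0)
  if (n_ind > 0L) {
    at <- sample.int(B, n_ind)
    rd <- findInterval(at - 0.5, cum)
    off <- at - cum[rd]
    keep <- !duplicated(rd)
    rd <- rd[keep]; off <- off[keep]
    type <- sample(c("del", "ins"), length(rd), replace = TRUE)
    len <- 1L + rgeom(length(rd), 0.7)
    for (i in seq_along(rd)) {
      r <- rd[i]; L <- nchar(bases[r])
      o <- min(off[i], L - 1L)  # keep at least one flanking base each side
      if (o < 1L) next
      if (type[i] == "del") {
        dl <- min(len[i], L - o - 1L)  # keep a trailing aligned base
        if (dl < 1L) next
        bases[r] <- paste0(substr(bases[r], 1L, o),
                           substr(bases[r], o + dl + 1L, L))
        cigar[r] <- paste0(o, "M", dl, "D", L - o - dl, "M")
      } else {
        ins <- random_dna(1L, len[i])
        bases[r] <- paste0(substr(bases[r], 1L, o), ins,
                           substr(bases[r], o + 1L, L))
        cigar[r] <- paste0(o, "M", len[i], "I", L - o, "M")
      }
    }
    ind_read <- rd
  }

  # tag sequencing errors
  n_te <- rbinom(1L, n_reads * cfg$tag_length, cfg$tag_error_rate)
  if (n_te > 0L) {
    at <- sample.int(n_reads * cfg$tag_length, n_te)
    r <- ((at - 1L) %/% cfg$tag_length) + 1L
    o <- ((at - 1L) %% cfg$tag_length) + 1L
    for (i in seq_len(n_te)) {
      cur <- substr(read_tag[r[i]], o[i], o[i])
      substr(read_tag[r[i]], o[i], o[i]) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }

  reads <- tibble(
    read_id = paste0("r", seq_len(n_reads)),
    tag = read_tag,
    chrom = chrom[mol_of_read],
    start = as.integer(start[mol_of_read]),
    strand = strand[mol_of_read],
    cigar = cigar,
    bases = bases,
    quals = strrep("I", nchar(bases))
  )

  truth <- list(
    molecules = tibble(molecule_id = seq_len(n_mol), tag = tag, chrom = chrom,
                       start = as.integer(start), length = frag_len,
                       strand = strand, n_reads = sizes,
                       spike_variant = spike_of_mol),
    variants = variants,
    reads = tibble(read_id = reads$read_id,
                   molecule_id = mol_of_read,
                   n_subst = tabulate2(sub_read, n_reads),
                   has_indel = seq_len(n_reads) %in% ind_read),
    n_input_molecules = n_input,
    seed = seed
  )
  list(reads = reads, truth = truth)
}

tabulate2 <- function(idx, n) {
  if (length(idx) == 0L) return(integer(n))
  tabulate(idx, nbins = n)
}

empty_reads <- function() {
  tibble(read_id = character(), tag = character(), chrom = character(),
         start = integer(), strand = character(), cigar = character(),
         bases = character(), quals = character())
}

empty_variant_truth <- function(cfg) {
  si <- cfg$spike_ins
  if (is.null(si) || nrow(si) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), vaf = numeric(), n_covering = integer(),
                  n_alt = integer(), realized_vaf = numeric()))
  }
  mutate(si, n_covering = 0L, n_alt = 0L, realized_vaf = 0)
}

#' Rebuild raw (untagged) reads from tagged reads
#'
#' Prepends the tag to the insert and appends the duplex adapter, producing
#' the raw-read form consumed by [extract_tag()]. Used to exercise the tag
#' extraction stage against simulator truth.
#'
#' @param reads tagged-read tibble
#' @param spec an [adapter_spec()]
#' @param adapter_mismatches number of substitutions to plant inside each
#'   appended adapter copy (tests mismatch-tolerant trimming)
#' @return raw-read tibble (`read_id`, `chrom`, `start`, `strand`, `bases`,
#'   `quals`)
#' @export
as_raw_reads <- function(reads, spec = adapter_spec(), adapter_mismatches = 0L) {
  ad <- spec$duplex_adapter_seq
  ads <- rep(ad, nrow(reads))
  if (adapter_mismatches > 0L && nrow(reads) > 0L) {
    for (i in seq_along(ads)) {
      pos <- sample.int(nchar(ad), adapter_mismatches)
      for (p in pos) {
        cur <- substr(ads[i], p, p)
        substr(ads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
    }
  }
  tibble(
    read_id = reads$read_id,
    chrom = reads$chrom,
    start = reads$start,
    strand = reads$strand,
    bases = paste0(reads$tag, reads$bases, ads),
    quals = paste0(strrep("I", nchar(reads$tag)), reads$quals,
                   strrep("I", nchar(ads)))
  )
}

#' Simulate a cohort: mutation-free normals plus a spike-in dilution series
#'
#' Writes one tabular read file and one JSON truth manifest per sample under
#' `out_dir`, plus a dataset README echoing the configuration. Per-sample
#' seeds are derived deterministically from the master seed, so the cohort
#' is reproducible sample-by-sample.
#'
#' @param cfg a [simulation_config()]; its `spike_ins` (if any) supply the
#'   variant positions for the dilution series
#' @param out_dir output directory (created; must not already contain
#'   samples of the same names)
#' @param n_normals number of mutation-free samples
#' @param spike_series VAF levels for the dilution series (use
#'   `numeric(0)` for none); each level is simulated `n_duplicates` times
#' @param n_duplicates replicates per dilution level
#' @return tibble describing the written samples (`sample`, `kind`, `vaf`,
#'   `seed`, `reads_path`, `manifest_path`)
#' @export
simulate_cohort <- function(cfg, out_dir, n_normals,
                            spike_series = c(0.05, 0.01, 0.005, 0.001, 0),
                            n_duplicates = 2L) {
  assert_that(n_normals >= 1L, "n_normals must be >= 1")
  master <- cfg$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  plan <- bind_rows(
    tibble(kind = "normal", vaf = NA_real_, rep = seq_len(n_normals)),
    if (length(spike_series) > 0L && !is.null(cfg$spike_ins))
      tidyr::expand_grid(vaf = spike_series, rep = seq_len(n_duplicates)) |>
        mutate(kind = "spike")
  )
  plan <- mutate(plan,
    sample = ifelse(.data$kind == "normal",
                    sprintf("normal_%03d", .data$rep),
                    sprintf("spike_%g_rep%d", .data$vaf * 100, .data$rep)),
    seed = derive_seed(master, row_number()))

  files <- purrr::pmap(plan, function(kind, vaf, rep, sample, seed) {
    scfg <- cfg
    if (kind == "normal") {
      scfg$spike_ins <- NULL
    } else {
      scfg$spike_ins$vaf <- vaf
    }
    sim <- simulate_sample(scfg, seed = seed)
    rp <- file.path(out_dir, paste0(sample, ".reads.tsv"))
    mp <- file.path(out_dir, paste0(sample, ".manifest.json"))
    assert_that(!file.exists(rp), paste0("output path collision: ", rp))
    write_tagged_reads(sim$reads, rp)
    write_manifest(sim$truth, mp)
    tibble(sample = sample, kind = kind, vaf = vaf, seed = seed,
           reads_path = rp, manifest_path = mp)
  })
  out <- bind_rows(files)
  writeLines(c(
    "Synthetic tagged-read cohort",
    paste0("generated: plasmacall ", pkg_version()),
    paste0("master seed: ", master),
    paste0("samples: ", nrow(out)),
    paste0("config: ", jsonlite::toJSON(config_echo(cfg), auto_unbox = TRUE))
  ), file.path(out_dir, "README.txt"))
  readr::write_tsv(out, file.path(out_dir, "samples.tsv"))
  out
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 16807) %% 2147483563)
}

config_echo <- function(cfg) {
  e <- unclass(cfg)
  e$reference <- paste0("<", length(e$reference), " contig(s), ",
                        sum(nchar(e$reference)), " bp>")
  e$panel <- paste0("<", nrow(cfg$panel), " interval(s), ",
                    sum(cfg$panel$end - cfg$panel$start), " bp>")
  if (!is.null(e$spike_ins)) e$spike_ins <- as.list(e$spike_ins)
  e
}

write_manifest <- function(truth, path) {
  jsonlite::write_json(
    list(molecules = truth$molecules, variants = truth$variants,
         reads = truth$reads, n_input_molecules = truth$n_input_molecules,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
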