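# Desk-scale validation experiment: specificity on held-out mutation-free
# cohorts and sensitivity on a spike-in dilution level, mirroring the
# assay-validation design (control cohort for the error profile, held-out
# normals for specificity, duplicate spike-in samples for sensitivity).

#' Simulate a sample and carry it to an SSCS pileup
#'
#' Convenience wrapper for the common chain: simulate, restrict to panel,
#' collapse families, pile up.
#'
#' @param cfg a [simulation_config()]
#' @param seed sample seed
#' @param consensus a [consensus_config()]
#' @return list with `pileup`, `truth`, `n_reads`, `n_sscs`
#' @export
simulate_pileup <- function(cfg, seed = cfg$seed,
                            consensus = consensus_config()) {
  sim <- simulate_sample(cfg, seed = seed)
  reads <- filter_on_panel(sim$reads, cfg$panel)
  sscs <- collapse_families(reads, consensus)
  pile <- build_pileup(sscs, cfg$panel, cfg$reference)
  list(pileup = pile, truth = sim$truth,
       n_reads = nrow(reads), n_sscs = nrow(sscs))
}

#' Run the specificity / sensitivity validation experiment
#'
#' Simulates a training cohort of mutation-free normals, builds the
#' background error profile from it, then (a) calls a held-out cohort of
#' mutation-free samples to measure variant-level specificity (fraction of
#' tested position-allele hypotheses without a false PASS call) and
#' sample-level specificity (fraction of samples with zero PASS calls), and
#' (b) calls duplicate spike-in samples at one dilution level to measure
#' sensitivity. All per-sample seeds derive from `seed`.
#'
#' @param seed master seed
#' @param reference,panel study region; defaults to a 1000 bp synthetic
#'   contig with a single 300 bp target interval derived from `seed`
#' @param n_train training normals for the error profile
#' @param n_test held-out mutation-free samples
#' @param n_spike_replicates duplicate spike-in samples (0 disables)
#' @param spike_vaf dilution level for the spike-in samples
#' @param n_spike_variants spiked SNVs spread across the panel
#' @param input_mass_ng,recovery,family_size_mean,raw_substitution_rate,raw_indel_rate,tag_error_rate
#'   generator settings passed to [simulation_config()]
#' @param profile_cfg a [profile_config()]
#' @param caller_cfg a [caller_config()]
#' @param progress emit one message per processed sample
#' @return list: `variant_specificity_pct`, `sample_specificity_pct`,
#'   `n_hypotheses`, `n_false_pass`, `held_out` (per-sample tibble),
#'   `spike` (per replicate x variant tibble), `profile_glance`,
#'   `reference`, `panel`, `spike_variants`
#' @export
run_validation_experiment <- function(seed,
                                      reference = NULL, panel = NULL,
                                      n_train = 60L, n_test = 60L,
                                      n_spike_replicates = 2L,
                                      spike_vaf = 0.005,
                                      n_spike_variants = 6L,
                                      input_mass_ng = 50,
                                      recovery = 0.221,
                                      family_size_mean = 3,
                                      raw_substitution_rate = 1e-4,
                                      raw_indel_rate = 1e-4,
                                      tag_error_rate = 1e-3,
                                      profile_cfg = profile_config(),
                                      caller_cfg = caller_config(),
                                      progress = FALSE) {
  if (is.null(reference)) {
    reference <- simulate_reference(1000L, "sim1", seed = derive_seed(seed, 1L))
  }
  if (is.null(panel)) {
    panel <- tibble(chrom = names(reference)[1], start = 350L, end = 650L)
  }
  cfg <- simulation_config(reference, panel,
                           input_mass_ng = input_mass_ng, recovery = recovery,
                           family_size_mean = family_size_mean,
                           raw_substitution_rate = raw_substitution_rate,
                           raw_indel_rate = raw_indel_rate,
                           tag_error_rate = tag_error_rate)

  note <- function(...) if (progress) inform(sprintf(...))

  controls <- purrr::map(seq_len(n_train), function(i) {
    note("training normal %d/%d", i, n_train)
    simulate_pileup(cfg, seed = derive_seed(seed, 100L + i))$pileup
  })
  profile <- build_error_profile(controls, profile_cfg)

  held_out <- purrr::map(seq_len(n_test), function(i) {
    note("held-out normal %d/%d", i, n_test)
    sp <- simulate_pileup(cfg, seed = derive_seed(seed, 10000L + i))
    res <- call_variants(sp$pileup, profile, caller_cfg)
    tibble(sample = i, m = res$m,
           n_pass = sum(res$calls$filter == "PASS"))
  }) |> bind_rows()

  n_hyp <- sum(held_out$m)
  n_false <- sum(held_out$n_pass)

  spike <- tibble()
  spike_variants <- tibble()
  if (n_spike_replicates > 0L) {
    spike_variants <- pick_spike_variants(reference, panel,
                                          n = n_spike_variants,
                                          vaf = spike_vaf)
    scfg <- cfg
    scfg$spike_ins <- spike_variants
    spike <- purrr::map(seq_len(n_spike_replicates), function(r) {
      note("spike replicate %d/%d", r, n_spike_replicates)
      sp <- simulate_pileup(scfg, seed = derive_seed(seed, 20000L + r))
      res <- call_variants(sp$pileup, profile, caller_cfg)
      pass <- pass_calls(res)
      spike_variants |>
        mutate(replicate = r,
               called = paste(.data$chrom, .data$pos, .data$alt) %in%
                 paste(pass$chrom, pass$pos, pass$alt),
               measured_vaf = pass$vaf[match(
                 paste(.data$chrom, .data$pos, .data$alt),
                 paste(pass$chrom, pass$pos, pass$alt))],
               realized_vaf = sp$truth$variants$realized_vaf)
    }) |> bind_rows()
  }

  list(
    variant_specificity_pct = 100 * (1 - n_false / n_hyp),
    sample_specificity_pct = 100 * mean(held_out$n_pass == 0L),
    n_hypotheses = n_hyp,
    n_false_pass = n_false,
    held_out = held_out,
    spike = spike,
    profile_glance = glance(profile),
    reference = reference,
    panel = panel,
    spike_variants = spike_variants
  )
}
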