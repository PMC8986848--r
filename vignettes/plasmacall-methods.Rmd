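---
title: "Consensus collapsing and error-profile variant calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus collapsing and error-profile variant calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmacall)
library(tibble)
```

`plasmacall` detects low-frequency somatic variants in cell-free DNA
(cfDNA) from molecular-tag targeted sequencing. This vignette explains the
statistical model, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where the
methodology left room.

## 1. From reads to single-strand consensus sequences

Each sequencing read carries a molecular tag ligated before amplification,
so all reads descending from one original cfDNA strand share a tag. Reads
are grouped into **families** keyed by (tag, chromosome, alignment start,
strand):

- The alignment **start** anchors the family because single-end reads have
  one well-defined fragment end; cfDNA fragments are short (~160 bp), so a
  (tag, start) pair identifies a molecule for all practical purposes.
- **Strand** is the alignment orientation; forward and reverse families
  are never merged, because each represents one strand of the original
  duplex. The pipeline produces single-strand consensus sequences (SSCS)
  only — no duplex consensus, which the underlying single-end chemistry
  cannot provide.

Sequencing errors *inside the tag* split one molecule into several
families and inflate apparent molecule counts. Within one (chromosome,
start, strand) locus, a family whose tag lies within Hamming distance 1
(configurable) of a *strictly larger* family's tag is absorbed into it —
the directional rule long established in UMI deduplication. Equal-sized
neighbours are left alone: with no size signal the merge direction would
be arbitrary, and leaving two molecules is the conservative reading.
Ties among several larger candidates break lexicographically by tag, so
the operation is deterministic.

Each family is collapsed by a per-position vote over the members covering
that position: an allele is accepted only when its fraction **strictly
exceeds** `majority_threshold` (default 0.70); otherwise the consensus
base is `N`, which contributes to neither allele counts nor coverage.
A family of 10 reads with 7 carrying an allele — exactly 70.0% — yields
`N`; 8 of 10 yields the allele. The same vote applies to deletions and
insertions of any length (per event). Members whose CIGAR disagrees at a
segment simply vote their own expanded alleles there, which acts as an
"other" vote against every concrete allele — conservative and easy to
reason about. Voting is over *covering* members, not all members, so a
shorter read does not dilute votes at positions it never observed.
`min_family_size` defaults to 1: a single read still represents one
molecule, and the downstream caller — not a family-size rule — decides
what is believable.

Numerical detail: the strict ">70%" comparison is computed as
`count/denominator − threshold > 1e-9` so that exact boundary fractions
can never win through floating-point rounding, while any genuine
exceedance (at least `1/denominator` above the threshold) always does for
any realistic family size.

## 2. The background error profile

Even at consensus level, residual errors survive (mostly from singleton
families, where the vote is vacuous). The caller therefore tests each
candidate against a position- and allele-specific background estimated
from mutation-free control plasma samples: pooled counts `k` (alternative
SSCS observations) out of `n` (SSCS coverage) per (position, alternative
allele), strands pooled — strand balance is enforced separately at call
time, and pooling doubles `n` per entry. Indel background is keyed by
(position, indel type, length class) rather than exact sequence, keeping
`n` usable; an indel class never seen in any control is tested against
`k = 0` at the position's pooled coverage. Known-SNP positions are
excluded from both profiling and testing.

At consensus-level error rates most positions have `k = 0`, and a plug-in
rate of zero would make any single supporting molecule "significant". The
profile therefore stores an **upper confidence bound** `ε_up` at
per-entry confidence `δ` (default 0.01). Two bounds are implemented:

- `exact` (default): the one-sided Clopper–Pearson binomial bound,
  `qbeta(1 − δ, k + 1, n − k)`. At `k = 0` it behaves like
  `ln(1/δ)/n` — with 60 controls at ~2000× coverage (`n = 1.2e5`),
  about `4e-5`.
- `massart`: the additive sub-Gaussian concentration bound with the sharp
  constant, `k/n + sqrt(ln(1/δ)/(2n))` — about `4.4e-3` at the same `n`.

Both dominate `k/n`, are monotone in `k` and `n`, and fail to cover the
true rate with probability at most `δ`. The package defaults to the exact
bound: the additive form's `O(n^{-1/2})` radius is so wide at realistic
control-cohort sizes that a 0.5% VAF variant (expected ~10 supporting
molecules at 2000× coverage) cannot reach significance against it, while
the exact bound's `O(n^{-1})` behaviour preserves that sensitivity at the
same coverage guarantee. The additive bound remains available for
sensitivity analyses. Either way the profile sharpens as control cohorts
grow — the estimated profile approaches the true one — which is why the
caller performs better with more normals.

## 3. The caller

For a sample pileup, every non-SNP position with SSCS coverage at least
`min_sscs_coverage` (default 100; shallower positions are not considered
at all) and background coverage in the profile contributes three SNV
hypotheses — one per alternative allele — to the testing universe `m`;
observed indel classes of length ≥ `min_indel_length` (default 3) add one
each. A candidate with alternative count `x` at coverage `c` gets the
one-sided binomial tail `p = P(X ≥ x | X ~ Bin(c, ε_up))` via the stable
survival function, then `p_adj = min(1, m · p)` (Bonferroni). Counting
*all* testable hypotheses in `m` — not only candidates with nonzero
counts — is the stringent reading of controlling the global (per-sample)
false-positive rate: it bounds the probability that a wild-type sample
produces any PASS call by `α` (default 0.05; ties at `p_adj = α` are not
called). The universe is counted per sample and recorded in the run
metadata.

Significant candidates then pass a filter chain, each failure labelled in
the output (an empty set is `PASS`): dual-strand support
(`single_strand`), a two-sided exact strand-bias test on
`[[alt_f, cov_f − alt_f], [alt_r, cov_r − alt_r]]` with floor 0.001
(`strand_bias`; both the statistic and the floor are configuration
knobs, since "limited strand bias" admits many parameterisations), and
the indel length rule (`indel_too_short`, emitted untested for
visibility). Filters only remove calls, never add them, so relaxing any
filter cannot reduce the PASS set. Calls are a deterministic function of
(pileup, profile, configuration). Output is VCF v4.2 (1-based,
left-anchored indels), a TSV mirror, and a JSON metadata file recording
`m`, `α`, and a profile checksum. Downstream annotation — synonymous
filtering, clonal-hematopoiesis adjudication, gene consequences — is
deliberately out of scope; the caller emits all somatic candidates.

## 4. The synthetic-data generator

The generator emulates the validation design of a tag-based capture assay
end to end: molecule counts from input mass (2 single strands per genome
equivalent at 3.3 pg per haploid genome) thinned by a molecular-recovery
fraction (default 0.221, a realistic capture-library figure); ~160 bp
fragments with ±20 bp uniform jitter placed uniformly among positions
overlapping the panel; uniformly random 10 nt tags (collision handling is
deliberately the consensus module's job); strand assigned symmetrically;
spike-in variants allocated binomially at their nominal VAF among
covering molecules; reads per molecule from a configurable family-size
distribution; independent per-base substitution, indel and tag errors;
and a truth manifest tying every read to its molecule and recording
realized next to nominal VAFs. Everything is reproducible from a single
master seed with per-sample derived seeds.

Two distribution choices deserve justification:

- **Family sizes** default to a zero-truncated Poisson around the
  configured mean (default 3), with a geometric alternative. After
  capture, the library is sequenced to a roughly fixed depth, so reads
  per recovered molecule concentrate around the mean rather than
  following the heavy singleton mass of a pure branching (geometric)
  process; at mean 5 the singleton fraction is ~3.5% versus 20% for the
  geometric, and singletons are exactly the families where consensus
  cannot suppress errors.
- **Error injection** is strand- and position-homogeneous. Real Ion
  semiconductor data has flow-space homopolymer structure and
  position-specific hotspots; the generator makes no attempt at either
  (a hotspot table can be emulated by raising the indel/substitution
  knobs). Consequently, passing tests demonstrate the statistical
  machinery — error suppression, bound coverage, family-wise error
  control — under honest homogeneous noise, not performance on real
  flow-space artifacts.

## 5. Study-scale choices

The validation experiments (test suite and `scripts/acceptance.R`) run at
desk scale: one synthetic 1000 bp contig with a single 300 bp target
interval; 50 ng input at 22.1% recovery (~6700 molecules per sample,
interior SSCS coverage ~2300, matching the ~2200× median of clinical-scale
runs); per-base substitution rate 1e-4 for the specificity/sensitivity
experiments; 60 training normals, 60 held-out mutation-free samples
(~54,000 tested hypotheses), and duplicate spike-in samples with six SNVs
at 0.5% VAF. The error-suppression ordering experiment uses raw error
1e-3 and mean family size 5, where the consensus layer alone yields a
≥10× rate reduction. These sizes were chosen once as a faithful small
replica of the validation design; all quantities reported by the
acceptance script are recomputed from scratch at run time.

## 6. Degenerate inputs and numerical conventions

- Coordinates are 0-based half-open internally; 1-based only in
  VCF/TSV/BED emission and import.
- Consensus strings use `{A,C,G,T,N}` plus `-` at positions whose
  consensus is a deletion; deletion and insertion events are additionally
  reported as explicit (position, length, sequence) records, which is
  what the pileup and caller consume.
- Empty inputs return empty results, never errors (empty read files,
  zero-coverage positions); genuinely unusable configurations (zero
  controls, `n = 0` bounds, spike-ins off panel, mismatched panels,
  unknown configuration keys) fail loudly.
- Profile rates serialise at full double precision (`%.17g`) and are
  parsed back with `strtod`, so save/load round-trips are bit-exact.
- The coverage floor means positions with SSCS coverage < 100 are
  *absent* from the tested universe rather than emitted as filtered
  records, mirroring how such positions are excluded from calling
  altogether.

## 7. Known limitations

- No duplex (double-strand) consensus and no quality-weighted voting.
- The Bonferroni universe is per sample; cohort-level multiplicity across
  many samples is the analyst's responsibility.
- Indel background is length-class based; exact-sequence indel error
  profiles would need far deeper control cohorts than the method assumes.
- The generator's homogeneous error model understates position-specific
  artifact structure; specificity measured on it is an upper bound on
  what position-heterogeneous noise would give *unless* the control
  cohort captures that heterogeneity — which is precisely what the
  per-position profile is designed to do on real data.
- Molecular recovery uses median SSCS coverage as "recovered molecules";
  with fragments longer than the reported position's neighbourhood this
  undercounts molecules that only graze the panel. The convention and its
  constants are echoed in every report.
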