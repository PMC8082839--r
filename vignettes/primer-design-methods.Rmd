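---
title: "Specificity-screened primer design: models, parameters and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specificity-screened primer design: models, parameters and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(primerscreen)
```

`primerscreen` screens every candidate primer in a multi-sequence DNA
database for thermodynamic suitability and database-wide specificity, then
ranks all surviving forward/reverse pairs per target sequence. This
vignette is the package's own account of the underlying models, the
parameters that matter, the design decisions that were genuinely open, and
what the verification suite does and does not establish.

## The pipeline and its data model

Every subsequence of length `min_len..max_len` (default 19–23 bp) of every
sequence is a candidate, on both strands. An antisense candidate is stored
as the reverse complement of its sense window, tagged `*`; its position
remains the sense-strand window start, so a single 0-based, half-open
coordinate system serves both orientations and makes amplicon arithmetic
trivial (`product = rp_pos + |RP| − fp_pos`). Windows containing non-ACGT
bases are skipped: they cannot be synthesized as primers and have no
nearest-neighbor parameters. Candidates aggregate into a sidset table: one
row per distinct tagged string with the sorted set of sequence IDs it
occurs in. Tagged and untagged keys are deliberately distinct — the tag is
orientation metadata, and all sequence comparisons downstream operate on
the untagged string.

The filters communicate through one mutable structure, the primer index,
whose `valid` flag is monotone: every stage may only clear it. This makes
the stage order irrelevant to the final verdict and is the basis of the
scheduling-invariance guarantee below.

## Melting temperature and 3'-end stability

The classic constraint set for single primers (melting temperature, GC
content, self-complementarity, 3'-end self-complementarity, contiguous
residue, Gibbs free energy) fixes *which* quantities are screened but not
their formulas. The package uses the de facto standard:

* **Tm** — nearest-neighbor model with the unified DNA/DNA stack table
  (SantaLucia 1998): `Tm = 1000·ΔH / (ΔS′ + R·ln(C/4)) − 273.15`, with the
  entropic salt correction `ΔS′ = ΔS + 0.368·N_stacks·ln[Na+]`. Defaults:
  oligo concentration 50 nM, monovalent cations 50 mM. The stack table
  ships as a plain-text file (`inst/extdata/nn_params.txt`) so it can be
  inspected or replaced wholesale; `thermo_params(path = ...)` loads an
  alternative. The table is complement-symmetric, so `Tm(P) =
  Tm(revcomp(P))` holds exactly — a property the tests exploit.
* **ΔG(3′ end)** — the summed ΔG37 of the four stacks spanned by the last
  five bases. Five bases is the common 3'-end-stability convention; the
  threshold (≥ −9 kcal/mol by default) rejects overly sticky,
  misprime-prone ends. For toy primers shorter than five bases the window
  is undefined and the predicate passes vacuously.
* **Dimer scores** — `comp_any(P, Q)` is the maximum number of
  Watson–Crick complementary aligned positions over all ungapped offsets
  of `P` against the reverse of `Q`; `comp_end` restricts to alignments
  that pair the 3'-terminal base of `P` and scores the contiguous run
  ending there. Unit weights were chosen over the weighted halves some
  tools use because the brute-force definition is directly checkable by
  exhaustive enumeration — which the suite does for every ACGT string up
  to length 8.

No divalent-cation (Mg²⁺) correction is modeled; see *Limitations*.

When a primer fails several constraints the reported reason is the first
violation in a fixed order — contiguous residue, GC content, Tm, self-any,
self-end, ΔG — chosen so the cheap compositional predicates are named
before the thermodynamic ones. The pass/fail verdict itself is
order-independent, and a property test verifies that it equals the
conjunction of the six individually evaluated predicates.

## Cross-hybridization filtering

A primer is unsafe when a sequence it does *not* target contains a site
similar enough to anneal. Two complementary filters implement this.

**3'-anchored (5' mismatch) filtering.** Annealing tolerates 5' mismatches
far better than 3' ones, so a primer whose 3'-anchored suffix (all but the
first `trim_depth = 4` bases, clamped so the suffix is never empty) occurs
in any sequence outside its sidset is invalidated. The suffix index maps
each suffix to the primers carrying it; every sidset-table row probes the
index, and a hit with a different untagged string whose probe sidset is not
contained in the primer's sidset clears the flag. All rows probe —
including rows whose own primer already failed. Skipping known-invalid
probes is available (`probe_skip_invalid`) but off by default: the skip is
an order-dependent shortcut, and probing all rows makes the result
independent of probe order.

**General filtering with pigeonhole seeds.** For mismatch tolerance `k`, a
primer of length |P| is split into `k+1` disjoint seeds of length
`⌊|P|/(k+1)⌋` at offsets `0, s, …, k·s` (trailing remainder bases yield no
seed). If two equal-length strings differ in at most `k` positions, at
least one seed pair is identical at the same offset — so grouping primers
and probe rows by the serialized key `seed+index+|P|` and comparing only
within groups finds every off-target pair with no false negatives. The
suite's central property is that this seed-indexed filter is *bit
identical* to a quadratic scan of all same-length window pairs — exact
equivalence, not an approximation. Rounds run for `k = 1` then `k = 2`
(the customary maximum); each round rebuilds the seed index from the
current snapshot and merges its invalidations afterwards, so within a
round invalidations never remove probes. The mismatch test uses `≤ k`,
so a site already caught at `k = 1` is harmlessly re-found at `k = 2`.

Two boundary conventions worth stating: equal sidsets never invalidate (a
primer cannot be its own off-target), and an untagged/tagged pair with
identical letters but different sidsets *does* invalidate in the general
filter — the stripped strings are equal at distance 0 with an off-target
occurrence. In the 3'-anchored filter the worked example implies the
opposite convention (identical stripped strings are skipped), and that is
what is implemented there.

## Scheduling: deterministic parallel contract

Key groups are sorted ascending by group size (*workload order*, ties
broken lexicographically by serialized key for determinism) and partitioned
into contiguous chunks only at group boundaries; the greedy
cumulative-share rule bounds each chunk's load by `⌈total/n⌉` plus one
group. Probe rows stream through each chunk in batches. Because every
batch's result is a set of invalidated primers and the merge is a union
(an AND on validity flags), the final state is identical for every worker
count, batch size and processing order — the suite verifies byte-identical
ranked output across worker counts {1, 2, 4, 8} × batch sizes {1, 37, all}.
The workload percentile thresholds (85th percentile at `k = 1`, 20th at
`k = 2`, nearest-rank rule) classify groups into small-unit and large-unit
work — per-item versus subdivided tasks on skewed group-size
distributions; the classification tunes granularity only and cannot affect
results. The pairing stage orders target groups by forward-primer count
and uses a two-threshold (small/large percentile) classification the same
way.

## Pairing and penalties

Surviving occurrences group by target sequence (`sid`); forward = untagged,
reverse = tagged. Every forward × reverse combination is screened: length
difference ≤ 5 bp, Tm difference ≤ 3 °C, forward strictly upstream and
non-overlapping, product size within 100–250 bp (the standard qPCR amplicon
convention), and the three cross-dimer bounds. Grouping is by single target
sequence (`sid`) by default; a stricter variant that additionally requires
both primers of a pair to share their *entire* target set — the natural
choice when a pair is meant to amplify a whole family of sequences — is
available as `group_by = "sidset"`. Penalties are Primer3-style weighted absolute deviations from
optima (21 bp, 60 °C, 50 % GC; weights `w_len = w_tm = w_tmdiff = 1`,
`w_gc = w_prod = 0` — the exact production weight vector of the original
tools is not published, so the formula family is fixed and the vector is
configuration). Invalid combinations carry a `−1` sentinel score
internally and never reach output. Ranking is per target, ascending
penalty, with a total deterministic tie-break (forward string, reverse
string, positions).

## The synthetic generator and the verification studies

`generate_db()` draws i.i.d. sequences with a configurable GC bias;
`plant_offtarget()` copies a primer-length window from one sequence into
another with exactly `d` substitutions, recording ground truth. A `d = 0`
plant is an exact repeat: it extends the host primer's sidset and must
*not* trigger the general filter. A `1 ≤ d ≤ k` plant creates an
off-target site the `k`-round must catch. Manifests record only planted
events — full expected validity always comes from the quadratic oracles,
because random sequences can contain unplanned near-matches.

The standard verification study uses 200 databases of 20 sequences × 500
bp at GC 0.5 with primer lengths 19–23 and `k = 1, 2` — large enough that
every filter fires, small enough that the quadratic oracle runs in well
under a second per database. Host windows for planting are drawn from the
single-filter survivors so every planted event is observable downstream.

One configuration point deserves honesty: uniform random DNA is not
transcript-like. Its 19–23-mers melt around 53 °C under the monovalent-only
salt model, and unit-weight self-complementarity of random 20-mers centers
near 8, so the field-standard defaults (Tm 58–62 °C, self-any ≤ 5) leave
essentially no survivors on a random database — every downstream stage
would be tested against an empty set. `synthetic_benchmark_config()`
therefore widens exactly two bounds (minimum Tm 54 °C, self-any ≤ 6) and is
used for all synthetic studies; it was fixed once, before the studies, and
is part of the package API so the studies are reproducible. Passing tests
on synthetic data show the *algorithmic* guarantees (equivalence,
invariance, monotonicity, planted-truth recovery); they do not show that
the default thermodynamic bounds are well-calibrated for real
transcriptomes, homologous gene families, or repeat-rich genomes, whose
off-target structure random sequences do not emulate.

## Numerical and degenerate-input conventions

* Ties everywhere break lexicographically (byte order) or by ascending
  position — no ordering in the package depends on hash iteration or
  locale.
* The suffix trim is clamped per primer (`t = min(trim_depth, |P| − 1)`)
  so a suffix is never empty; a length-1 primer keys on itself.
* `seed_length(plen, k)` requires `plen ≥ k + 1`; probe rows too short to
  seed are skipped (they cannot carry an equal-length match to any indexed
  primer).
* Empty inputs (no sequences passing, no valid primers, no pairs) flow
  through every stage and produce empty, correctly-typed tables; a
  `max_mismatch` of 0 skips the general filter entirely.
* Penalties are plain double arithmetic on quantities of magnitude ≤ 10³;
  the deterministic tie-break makes ranking reproducible across platforms
  despite floating-point equality ties being broken by string order, not
  by unstable sort order.

## Limitations

* The Tm model corrects for monovalent cations only; Mg²⁺ and dNTP
  corrections (Owczarzy-style) are not implemented, so absolute Tm values
  sit several degrees below calculators that include them. Screening is
  relative within a run, so rankings are unaffected; calibrate the Tm
  bounds to the model when porting wet-lab configurations.
* No secondary-structure folding, hairpin ΔG minimization, or probe
  (hydrolysis/TaqMan) design.
* Cross-dimer screening is within-pair only; interactions between primers
  of different targets in multiplex reactions are out of scope.
* The generator does not simulate exon structure, homologous families, or
  real transcriptome composition; real-database behavior of the *filters*
  is exact by construction, but survivor counts on real data will differ
  substantially from the synthetic studies.
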