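# primerscreen

Specificity-screened qPCR primer pair design for multi-sequence DNA
databases.

Designing primers against a database of related sequences (a set of CDS or
mRNA records, a panel of gene targets) is not just a per-primer
thermodynamics problem: a primer that is a perfect match for its target may
also anneal to a *different* sequence in the database and amplify it — a
cross-hybridization event that ruins quantification. `primerscreen`
enumerates every candidate primer in a database, applies the standard
single-primer filters, then removes every primer with a homologous site in
any sequence it does not already target, and finally filters, scores and
ranks all forward/reverse pairs per target. It is written for molecular
biologists and bioinformaticians who need exhaustive, database-wide primer
screening rather than one-sequence-at-a-time design.

## The method

For a database of sequences with IDs *sid*, every subsequence of length
*minLen..maxLen* of every sequence (both strands; antisense windows are
stored as tagged reverse complements `*P`) is a candidate occurrence
`P+sid+pos`, aggregated into a table of rows `P+sidset` where *sidset* is
the set of sequences containing `P`.

1. **Single filtering.** Six per-primer constraints: nearest-neighbor
   melting temperature `Tm = 1000·ΔH / (ΔS + R·ln(C/4)) − 273.15` (unified
   stack parameters, entropic salt correction `0.368·N·ln[Na+]`), GC
   content, self-complementarity (`any` and 3'-anchored `end` dimer
   scores), maximum homopolymer run, and 3'-end stability ΔG over the last
   five bases.
2. **5' cross-hybridization filtering.** A suffix index keyed on each
   primer's 3'-anchored suffix (all but the first `trim_depth` bases)
   invalidates any primer sharing that suffix with a subsequence occurring
   outside the primer's sidset — mismatches confined to the 5' end do not
   prevent mispriming.
3. **General cross-hybridization filtering.** For mismatch tolerance
   `k = 1..max_mismatch` (default 2), each primer of length |P| is split
   into `k+1` disjoint seeds of length ⌊|P|/(k+1)⌋. By the pigeonhole
   principle, any same-length window within Hamming distance `k` shares at
   least one seed exactly, at the same offset — so a seed index keyed by
   `seed+index+|P|` finds *every* candidate off-target pair, and each pair
   is invalidated when the probe's sidset is not contained in the primer's.
   The filter is exactly equivalent to the quadratic all-pairs scan, at a
   fraction of the cost.
4. **Pair filtering and ranking.** Per target, all forward × reverse
   occurrence combinations are screened (length difference, Tm difference,
   amplicon geometry and product size, cross-dimer scores) and survivors
   are ranked by a Primer3-style penalty
   `Σ w·|value − optimum| + w_ΔTm·|Tm_F − Tm_R|`.

Key groups are processed in *workload order* (ascending group size) and
partitioned across workers only at group boundaries; results are provably
identical for every worker count and batch size.

## A worked example

```r
library(primerscreen)

db  <- generate_db(n_seqs = 8, seq_len = 400, seed = 7)  # synthetic database
cfg <- synthetic_benchmark_config()                      # config for random-composition DNA
fit <- design_primers(db, cfg)
fit
#> <primer_design>
#>   8 sequences, 30400 candidate primer keys
#>   716 valid primers after all filters, 93 ranked pairs

glance(fit)
#> # A tibble: 1 × 6
#>   n_sequences n_candidates n_single n_valid n_pairs best_penalty
#>         <int>        <int>    <int>   <int>   <int>        <dbl>
#> 1           8        30400      716     716      93         10.4
```

30,400 candidate windows collapse to 716 primers that satisfy the single
filters; none of them has an off-target site in this random database (the
cross-hybridization filters would remove any that did — plant one with
`plant_offtarget()` to watch it happen), and 93 forward/reverse pairs
satisfy the pair constraints. `tidy(fit)` returns the ranked table — rank 1
per `sid` is the best pair for that target:

```r
tidy(fit)[, c("sid", "rank", "forward_primer", "product_size", "penalty")]
#> # A tibble: 93 × 5
#>     sid  rank forward_primer        product_size penalty
#>   <int> <int> <chr>                        <int>   <dbl>
#> 1     1     1 ACCTTAGAAACACACAGGGCG          250    15.6
#> 2     2     1 TGTATGTCCTTCGCCGCTAAT          186    10.5
#> ...
```

The penalty sums each primer's deviation from the configured optima (21 bp,
60 °C) plus the pair's Tm difference; `write_pairs(tidy(fit), "pairs.tsv")`
writes the full deterministic TSV. `autoplot(fit, "attrition")` shows the
per-stage survivor counts. A command-line front end is installed as
`exec/primerscreen` (`primerscreen design --in db.fa --out pairs.tsv`,
`primerscreen generate --n-seqs 20 --seq-len 500 --seed 1`).

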