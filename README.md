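# tcrfocus

Paired T cell receptor (TCR) repertoire analysis for before/after treatment
comparisons — originally motivated by bone-marrow repertoires at myeloma
diagnosis versus day +100 after autologous stem cell transplantation (ASCT),
but applicable to any paired clonotype tables. For repertoire bioinformaticians
and immunologists who already have upstream V(D)J-annotated clonotype tables
(AIRR Rearrangement TSV or Decombinator-style CSV) and want the downstream
comparative statistics.

## What it computes

Given paired samples, after equalising sequencing depth by iterative
subsampling without replacement (a multivariate hypergeometric draw over
clone counts, 100 iterations by default, deeper sample cut to the shallower
one's depth):

* **Rényi diversity spectra** — for clone frequencies $p_i$,
  $H_q = \tfrac{1}{1-q}\ln\sum_i p_i^q$ in nats over the grid
  $q \in \{0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, \infty\}$, with the closed
  forms $H_0=\ln S$, $H_1=-\sum_i p_i\ln p_i$, $H_\infty=-\ln\max_i p_i$;
  default depths 3000 reads (alpha chain) / 9000 (beta).
* **Clonal expansion** — a clone is *expanded* when its frequency strictly
  exceeds 1/1000; per-sample expanded proportions and threshold–count curves.
* **CDR3 similarity networks** — cosine-normalised amino-acid triplet
  spectrum kernel, $K(s,t)=\sum_u c_s(u)c_t(u)$ over overlapping 3-mers,
  similarity $K(s,t)/\sqrt{K(s,s)K(t,t)}$; edges at similarity ≥ 0.80 over
  each sample's top 50 expanded CDR3s; clusters are connected components of
  size ≥ 2. At 0.80, motif-free control CDR3s show near-zero clustering.
* **Clonotype persistence** — the fraction of post-treatment expanded
  clonotypes present at baseline at any frequency, under nucleotide
  (V/J/CDR3-nt) or amino-acid (CDR3-aa) identity keys.
* **A synthetic paired-repertoire generator** — Zipf clone sizes, a
  post-treatment richness bottleneck, rank-ordered persistence of expanded
  clones, an expansion boost, novel low-frequency clones, and plantable CDR3
  motif families with known ground truth.

## Worked example

```r
library(tcrfocus)

pr <- simulate_paired(paired_sim_config(patient_id = "T01", seed = 42))
pr$baseline
#> <tcr_repertoire> T01_BL (patient T01, alpha chain, BL)
#>   5000 clonotypes, 50000 total reads
pr$post
#> <tcr_repertoire> T01_post (patient T01, alpha chain, postASCT)
#>   2513 clonotypes, 20000 total reads

pb <- renyi_profile(pr$baseline, depth = 3000, n_iterations = 100, seed = 42)
pp <- renyi_profile(pr$post,     depth = 3000, n_iterations = 100, seed = 42)
data.frame(order = pb$order, baseline = round(pb$median, 3),
           post = round(pp$median, 3))
#>    order baseline  post
#> 1   0.00    6.569 6.332
#> 2   0.25    6.236 5.926
#> 3   0.50    5.756 5.348
#> 4   1.00    4.315 3.841
#> 5   2.00    2.554 2.315
#> 6   4.00    1.880 1.717
#> 7   8.00    1.621 1.481
#> 8  16.00    1.513 1.382
#> 9  32.00    1.465 1.338
#> 10 64.00    1.441 1.316
#> 11   Inf    1.419 1.296

expanded_clones(pr$baseline)$proportion_expanded  # 0.0138
expanded_clones(pr$post)$proportion_expanded      # 0.0183

shared_expanded_fraction(pr$post, pr$baseline, mode = "aa")
#> <overlap_result> patient T01 (alpha, aa keys): 46/46 post-expanded
#> clonotypes present at baseline (1.00)
```

Reading it: the post-treatment profile lies below baseline at **every**
Rényi order (median across 100 subsample iterations at depth 3000), so the
post repertoire is less diverse under richness, Shannon, Simpson and
dominance simultaneously; meanwhile the expanded proportion *rises*
(0.0138 → 0.0183) and all 46 post-expanded clonotypes already existed at
baseline — a contracted, more focused, persistent repertoire.

`run_cohort("manifest.tsv", "outdir")` runs every stage over a cohort
manifest (sample_id / patient_id / chain / timepoint / path) and writes
TSV tables plus PDF figures; `inst/cli/tcrfocus.R` exposes the same stages
as shell subcommands (`simulate`, `diversity`, `expand`, `cluster`,
`overlap`, `run`).

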