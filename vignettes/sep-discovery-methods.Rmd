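---
title: "Methods: SEP discovery filtering and quantitative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEP discovery filtering and quantitative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsieve)
```

# Scope and model

`sepsieve` implements the computational half of a proteogenomic workflow for
discovering small ORF-encoded peptides (SEPs, microproteins) from shotgun
proteomics. The upstream parts — enrichment chemistry, database search and
FDR estimation, feature detection — are taken as given: the pipeline ingests
a table of peptide-spectrum matches (PSMs) with q-values, the spectra they
were matched to, a reference proteome, a SEP database, and (for the
quantitative stage) a SEP-by-sample intensity matrix for a paired
tumor/normal cohort with tumor-grade labels.

The discovery core is an exclusion filter. A PSM supports a novel SEP only
if *none* of the following fires:

1. **q-value gate** — PSM confidence worse than 1% FDR (`q > 0.01`);
2. **annotation gate** — the bare peptide sequence occurs as an exact
   substring of any reference proteome record;
3. **length gate** — peptide shorter than 8 residues;
4. **spectral gates** — the matched spectrum shows fewer than 4 consecutive
   b or y fragment ions, or below 40% coverage of the theoretical b/y
   ladder.

A SEP is *identified* when at least one of its PSMs survives every gate.
Excluded PSMs are reported with their **first failing gate** in the order
above, so gate counts in the run summary always sum to the PSM count. The
gates are independent predicates: their order affects only the reported
reason, never the surviving set (asserted by test).

# Fragment chemistry

Neutral peptide mass is the sum of residue monoisotopic masses (standard
tables, 6 decimals), modification deltas, and one water (18.010565 Da).
Theoretical b ions carry the first *i* residues (plus any N-terminal
modification); y ions carry the last *j* residues plus water; `m/z =
(neutral + z·1.007276)/z`. Complementarity `b_i + y_(L−i) = M` is exact by
construction and tested to 1e-9 Da on random modified peptides.

Peak annotation matches each theoretical ion to the nearest observed peak
within a ±0.02 Da product-ion tolerance (the tolerance of the ingested
search results); each theoretical ion is matched at most once, peaks may
serve several ions. Fragment charges considered default to {1}, adding {2}
when the precursor charge is ≥3 — which charge states a manual inspector
counts is not standardized, so this is exposed as a parameter.

Three deliberate readings of the spectral criteria, each configurable:

* **Runs are counted within a single series.** "Four consecutive b or y
  ions" is read as four consecutive ions of one series (the stricter of the
  plausible readings, and the one matching common manual-inspection
  practice); the maximum of the b-run and y-run is reported.
* **Coverage denominator is fixed at 2·(L−1)** singly-indexed ions, however
  many charge states are searched, so the 40% threshold has the same
  meaning for every peptide length and charge configuration. An index
  counts once no matter how many charge states matched it.
* **Boundaries are retained.** The criteria are exclusions ("fewer than
  four", "less than 40%"), so a run of exactly 4 and coverage of exactly
  0.40 pass. Fixtures pinned at run 3 vs 4 and coverage 0.39 vs 0.40 are
  part of the acceptance suite.

No intensity floor is applied to peaks before matching; none is specified
for the manual-inspection procedure being formalized.

# Novelty and aggregation

The annotation gate uses exact substring membership against the supplied
reference FASTA, never crossing record boundaries. Isoleucine/leucine are
isobaric and indistinguishable by standard MS; an optional I/L-collapsed
mode maps both to one symbol before matching. The default is **off**:
"identical sequence" is read literally, and the option is there for users
who want the conservative behavior. Modifications are ignored for novelty —
the criterion is a sequence-identity criterion.

Peptide-to-SEP aggregation requires the peptide to be an exact substring of
the SEP's sequence; a PSM violating this is a configuration error (wrong
database), not an exclusion.

# SEP annotation

* **Start codon**: `ATG` is canonical; `CTG`, `GTG`, `TTG` are the
  near-cognate starts; other valid codons are `other`. Classes come from
  database metadata, not re-derived from genomic sequence.
* **Transcript class**: pass-through of the database annotation with a
  small synonym table (`mRNA` → `protein_coding`, `lnc_RNA` → `lncRNA`).
* **Instability index**: the ProtParam/Guruprasad dipeptide-weight method,
  `II = (10/L)·Σ DIWV(x_i, x_{i+1})`, with the published 400-entry DIWV
  table vendored verbatim; `II > 40` is called unstable, per convention.
  The test oracle is an independently structured dipeptide-keyed lookup.
* **Sequence coverage**: fraction of SEP residues covered by the union of
  *all* occurrences of the surviving peptides — coverage is a residue-set
  property, so repeated placements count.

# Quantitative stage

The stages run in a fixed order: normalization → imputation → fold changes
→ differential calls → grade profiles → clustering → AUC.

**Normalization** scales every sample column so its total of present
intensities equals the median column total. This preserves within-column
ratios, is idempotent, and leaves missing entries missing. A consequence
worth knowing: strong asymmetric planted effects shift column totals, so
total-abundance normalization compositionally attenuates large fold
changes — visible in the synthetic recovery runs where estimated effects
sit slightly below the planted 2 log2 units while remaining well above the
call threshold.

**Imputation** models missing-not-at-random dropout of low-abundance ions:
each missing entry is drawn uniformly from the column's observed values at
or below its 5th percentile. The 5% pool bound is the package's own
parameterization of "low-abundance resampling" (the procedure is named but
not parameterized upstream). Columns with fewer than 20 observed values
fall back to the column minimum with a warning. The seed is an explicit
argument; the sampler restores the caller's RNG state.

**Differential calling** uses a two-sided paired t-test on log2 intensities
across patients, with Benjamini–Hochberg q-values reported alongside. The
up/down call applies `p ≤ 0.05` and `|mean log2FC| ≥ 1` on the raw p-value,
matching the stated thresholds of the formalized workflow. A
negative-binomial count model (DESeq2) is inappropriate for continuous
LFQ intensities and is deliberately not used; the paired t-test on log2
data is the standard coherent choice and exposes the same thresholds.

**Grade-trend profiles** are per-SEP means of the per-patient log2 fold
change within each grade (II < III < IV), row-standardized. Per-grade means
(rather than per-sample profiles) are the default because the clustering
question is about grade-level trends; constant profiles are dropped before
standardization.

**Fuzzy c-means** is implemented in-package: alternating membership/center
updates minimizing `Σ u_ik^m ‖x_i − c_k‖²`, seeded initialization from `c`
random distinct rows, stopping when the objective decreases by less than
`tol = 1e-6` (cap 1000 iterations). Items coincident with a center receive
full membership there (the update's zero-distance limit). The in-package
implementation exists because the pipeline's contracts — a monotone
objective trajectory, byte-reproducibility under a seed — are part of the
tested surface; `e1071::cmeans` is the independent cross-check in the test
suite, never the implementation. Defaults `c = 8` clusters and fuzzifier
`m = 2` (the Bezdek default, since no fuzzifier-selection procedure is
prescribed); both configurable.

**AUC** is the Mann–Whitney statistic `U/(n1·n2)` with midrank tie credit,
computed per SEP with the per-patient log2 fold change as score. The binary
contrast behind a grade-trend AUC is genuinely under-determined; the
default is grade II versus grades III∪IV pooled (higher grades positive),
configurable to II versus IV. This is an interpretation, flagged as such.

# Synthetic data: what it emulates, and what it does not

The generator produces every input from a seed, with exact truth tables,
so the whole pipeline is testable offline.

*Discovery bundle.* Random reference proteins (uniform residue
composition, 200–400 aa); SEPs of 20–100 aa, half novel by default. Novelty
is enforced constructively — rejection sampling until no tryptic peptide of
length ≥8 occurs in the reference — and decoys are substrings of reference
records, so criterion 1 must kill them. Planted survivors carry complete,
exactly placed singly-charged ladders (jitter truncated at ±0.015 Da, noise
peaks ≥0.1 Th from every ladder ion); one planted exclusion per remaining
gate uses constructed spectra (alternating ions for the run gate, a bare
b1–b4 prefix for the coverage gate) on peptides whose ladder m/z values are
mutually separated by >0.05 Da, so no peak can be attributed to the wrong
ion. This makes the truth table exact rather than probabilistic: precision
and recall of 1 are the designed outcome, and any deviation is a defect.

*Quant bundle.* Eighteen patients (9 grade II, 3 III, 6 IV) with one tumor
and one normal sample each — the cohort structure the analysis targets.
Log-normal baselines (log2 intensity ~ N(20, 2)); planted up/down SEPs at
±2 log2 units and grade-monotone SEPs spanning 2 log2 units from grade II
to IV (10% of SEPs each by default); log2-scale Gaussian noise (sd 0.5);
MNAR dropout with logistic probability in log2 intensity (τ = 17, width 1,
max 30%), giving a few percent missingness concentrated in low-abundance
rows — realistic for LFQ at this depth.

Not emulated: chromatography, isotope envelopes, charge-state
distributions, co-eluting interference, peptide-level quantification
rollup, shared peptides between SEPs, and real amino-acid composition
biases. Passing tests therefore demonstrate the correctness of the
filtering logic and the statistical machinery under the stated noise
model — not search-engine behavior or enrichment chemistry on real tissue.

# Numerical choices and degenerate inputs

* Monoisotopic constants hard-coded to 6 decimals; proton 1.007276 Da —
  ample at a 0.02 Da tolerance.
* Nearest-peak wins on multiple candidates within tolerance; spectral
  similarity uses greedy nearest-pair matching with an
  argument-order-invariant tie-break, so the score is symmetric.
* Empty peak lists annotate to empty matches (not an error); an empty PSM
  table yields a zero-survivor summary, not a crash.
* Length-1 peptides have no fragments (error); sequences shorter than 2
  have no instability index (error).
* All seeded stages (`impute_low_abundance`, `fuzzy_cmeans`, the
  generators) restore the caller's RNG state and are byte-reproducible
  under a fixed seed.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: discovery bundles of 50 SEPs (20 reference proteins), a
2000-SEP null cohort for calibration of the paired t-test's type-I rate,
500-SEP planted cohorts for sensitivity, AUC and clustering, and
1000-peptide sweeps for the mass-chemistry oracles. These sizes give the
statistical checks tight binomial intervals while keeping a full run in
tens of seconds on one core.

# Known limitations

* The filter operates per-peptide against whatever reference FASTA is
  supplied; discriminating SwissProt from TrEMBL hits, or peptide- versus
  protein-level annotation policies, is the caller's database choice.
* Cross-database SEP redundancy is resolved by exact sequence equality
  only; no clustering of near-identical entries.
* The AUC grade contrast and the fragment-charge set for matching are
  interpretations, exposed as parameters rather than silently fixed.
* No FDR re-estimation after filtering: q-values are taken as ingested.

# A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
b <- simulate_discovery_bundle(cfg, "fixtures")
summ <- run_discovery(b$reference_fasta, b$sep_fasta, b$mgf, b$psm_tsv,
                      "report", run_config(seed = 7))
summ$n_identified_seps

qb <- simulate_quant(cfg, "fixtures")
res <- run_quant_analysis(qb$quant_tsv, qb$samples_tsv, "quantreport",
                          run_config(seed = 7))
res$summary$n_up
```
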