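---
title: "Species-resolved matrisome analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-resolved matrisome analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenomatrisome)
```

## The analysis model

`xenomatrisome` deconvolves the tumor-cell and stromal-cell contributions
to the extracellular matrix (ECM) of human-in-mouse xenograft tumors from
label-free shotgun proteomics. The central idea is that, after searching
MS/MS spectra against a combined human+mouse sequence database, each
detected tryptic peptide is either specific to one species or common to
both; species-specific peptides attribute signal to the tumor (human) or
the stroma (mouse), while common peptides contribute to identification but
not to attribution.

The pipeline stages, with their governing rules:

**In silico digestion and species specificity.** Trypsin cleaves
C-terminally to K or R but not before proline. The no-cleavage-before-P
convention is not universal among search engines, but matches the engine
family this analysis consumes scores from and standard practice. A peptide
is *shared* when its sequence occurs in the digests of both species'
databases after mapping residues through the active equivalence classes.
By default only isoleucine and leucine are merged: they are mass-identical,
so no mass spectrometer can distinguish them, and treating an I/L variant
pair as species-specific would fabricate attribution evidence. An optional
N/D class (off by default) can additionally absorb deamidation ambiguity,
relevant after PNGaseF deglycosylation which converts glycosylated Asn to
Asp; we leave it off because genuine N/D ortholog differences are real
attribution signal and deamidation is better handled at the PSM level.
Digest products are bounded to 6–50 residues — the usual tryptic search
window — and up to two missed cleavages, all configurable via
`xeno_params()`.

**Spectral FDR.** For each LC-MS/MS run (sample × fraction) and each
precursor charge state 2, 3, and 4 separately, the retained-score threshold
is the smallest observed score $t$ with
$\widehat{\mathrm{FDR}}(t) = \#\{\text{decoys} \ge t\} / \#\{\text{targets}
\ge t\} \le 0.016$. Decoys are full reversed sequences, one per target
entry. No $\pi_0$ correction is applied — the decoys/targets ratio is used
as is. Charge-1 precursors are not triggered for sequencing and charges
above 4 are excluded from searching, so both are dropped before
thresholding. If no threshold attains the target FDR the run/charge stratum
is filtered entirely (threshold $+\infty$, with a warning).

**Distinct peptides and protein grouping.** A distinct peptide is the
single highest-scoring instance of a bare peptide sequence; different
charge states, adjacent fractions, and modification variants (oxidized Met,
deamidated Asn, and so on) collapse onto it. Database entries sharing a
detected peptide *strictly longer than 8 residues* are grouped (connected
components of the protein–peptide graph). Within a group, every member
carrying at least one distinct peptide found in no other member of the
group spawns a subgroup — this is how the human and mouse orthologs of one
gene, or distinct isoforms, surface as separate `G.S` entries. Members with
no unique evidence join the highest-scoring subgroup whose peptide set
covers theirs; if no subgroup covers them they join the top-scoring one.
The protein score is the sum of its distinct peptide scores (individual
peptide scores are bounded by 25); groups are numbered by descending total
score and subgroups by descending subgroup score, with lexicographic
accession as the deterministic tie-break.

Two details the grouping rule leaves open were resolved as follows. First,
grouping uses *detected* peptides only, not the full theoretical digest:
the grouping rule is tied to identified spectra, and theoretical-digest
grouping would merge large homology families without any observed evidence.
Second, a peptide of 8 residues or fewer can match entries in two different
groups without joining them; since every distinct peptide must be counted
toward exactly one group, such a peptide is attributed to the group of its
highest-raw-score parent (ties broken lexicographically), and an entry left
with no attributed peptides is not reported.

**Protein-level filter.** Subgroups need score ≥ 20; afterwards the
effective cutoff rises until no decoy subgroup survives (protein-level
FDR of zero). Because peptide scores are capped at 25, this forces
multi-peptide support unless a single near-perfect peptide is the sole
match.

**Matrisome membership.** A protein belongs to a tumor's matrisome when
detected in both of the two biological replicates and by at least two
distinct peptides in one of the two. "Detected" means ≥ 1 distinct peptide
in that replicate, and the counts are totals (species-specific plus
common): membership is an identification question, not an attribution one.
The identical two-sample rule gates quantifiability.

**Quantification and the fivefold rule.** A protein's abundance per species
is the summed precursor-ion current (XIC) of its quantifiable
species-specific peptides: peptides shared across multiple subgroups of a
group are excluded (their signal cannot be apportioned), as are precursors
with poorly defined isotope clusters. Each precursor ion (peptide, charge)
contributes once per sample, summed across fractions, and intensities are
pooled across the two replicates of a tumor type before the ratio is
formed, yielding one origin call per protein per tumor type. With human
intensity $H$ and mouse intensity $M$: no species-specific evidence →
undetermined; $M = 0 < H$ → tumor-only; $H = 0 < M$ → stroma-only;
otherwise $r = H/M$ with $r \ge 5$ tumor-dominant, $r \le 1/5$
stroma-dominant, else similar. The boundary $r = 5$ counts as dominant
("at least fivefold"). No normalization between human and mouse ionization
efficiencies is applied — none is available for peptides of differing
sequence — and such label-free cross-species ratios should be read as
reliable only to within about twofold, which is why the fivefold threshold
is deliberately conservative. Calls are invariant to rescaling both
intensities and mirror exactly under swapping the species.

**Signatures.** Gene symbol — not accession — is the comparison key between
tumor types, case-insensitively with the human symbol as canonical
rendering, so the human and mouse forms of one protein collapse to one
biological entity. The two matrisomes are compared as exact gene sets
(shared / A-only / B-only partition the union). Over the shared genes,
origin calls are compared per gene; the default granularity is the coarse
three-class view (tumor / stroma / both), under which a move between
dominance and similarity within "both" does not count as a shift, with the
exact six-class comparison available via
`xeno_params(shift_granularity = "fine")`. Genes undetermined on either
side are reported as indeterminate rather than forced into either set. No
multiple-testing machinery is involved anywhere: the comparisons are
set-based presence/absence and ratio-threshold calls, not hypothesis tests.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated
against known ground truth. It emulates the structure of the real
experiment — two tumor types × two biological replicates, a combined
human+mouse database, target and decoy PSMs — with these models and
defaults (`sim_config()`):

* **Ortholog pairs.** 120 genes; human sequences drawn residue-wise from
  average vertebrate amino-acid frequencies at lengths 240–420; the mouse
  ortholog substitutes each non-K/R/P residue independently with
  probability 0.05, matching the ~90–95% sequence identity typical of
  human–mouse ECM orthologs. K, R, and P are never substituted or
  introduced, so both orthologs share one tryptic map and divergence
  controls only which peptides are species-specific — a deliberate
  simplification that keeps the ground-truth bookkeeping exact.
* **Study design.** 60% of genes occur in both tumor types and the
  remainder splits evenly — mirroring the roughly two-thirds-shared Venn
  structure seen in real tumor-matrisome comparisons. Origins cycle
  deterministically through 40% tumor-only, 25% stroma-only, 35% mixed
  (ratios cycling 10, 1, 1/10), and 30% of shared genes switch coarse
  origin between the types. These assignments are functions of the
  configuration alone, so `ground_truth_signature()` restates the expected
  answer without touching the random-number stream.
* **Abundance and detection.** Per (gene, type), abundance is log-normal
  (median 2×10⁷ ion-current units, log-sd 1) with a log-normal replicate
  multiplier (log-sd 0.2); each zero-missed-cleavage peptide of a species
  is detected with probability $0.92 \cdot \mathrm{logistic}((\log A -
  \log 2\times10^6))$ in the species-level abundance $A$ — a saturating
  curve emulating the detectability floor of low-abundance proteins.
  Simulated PSMs carry zero missed cleavages; missed-cleavage handling is
  exercised by dedicated digestion tests rather than the simulator.
* **Scores and nuisance processes.** Target scores are normal per charge
  (means 13/14/15 for z = 2/3/4, sd 3.5), decoy scores normal (means
  5/6/7, sd 2.5), both truncated to the engine's [0, 25] support; charges
  sample (0.55, 0.33, 0.12); 5% of rows are decoy matches; intensities
  carry multiplicative log-normal noise (log-sd 0.25); 2% of PSMs are
  flagged with poor isotope quality; Met-containing peptides occasionally
  (5%) yield an extra oxidized-Met PSM to exercise distinct-peptide
  collapsing.

`recovery_config()` switches every nuisance off (certain detection, zero
noise, zero decoys, mixed ratios 25 and 1/25, outside the ambiguous
(1/5, 5) band) — under it the pipeline must reproduce the configured gene
sets, Venn counts, and origin classes *exactly*, and the test suite and
acceptance script assert that it does.

What the simulator does **not** model — and hence what passing tests do not
show about real data: retention time, m/z, and spectrum-level effects
(merging of redundant spectra, precursor interference); correlated
peptide-level ionization efficiencies (real XIC ratios are biased per
peptide, the simulator's noise is unbiased); shared peptides across
*different* genes (paralog families), which in real searches create larger,
harder groups than random sequences do; contaminant entries; and
between-run normalization drift. Conclusions about calibration on real
data rest on the FDR machinery's distribution-free construction, not on
the simulator.

## Numerical and degenerate-input choices

* FDR thresholds scan only the observed score grid; with no qualifying
  threshold the stratum is emptied (threshold $+\infty$) with a warning
  rather than silently passing everything.
* A charge stratum with no target PSMs is an error, as is a PSM whose
  peptide occurs in neither database digest (these indicate a
  table/database mismatch, not a data feature).
* Ties everywhere (group numbering, subgroup ranking, representative
  choice, peptide attribution) break by lexicographic accession so results
  are bit-reproducible across platforms.
* Exactly-boundary cases are inclusive where the rules say "at least":
  membership (2, 1) passes, ratio 5.0 is dominant; the grouping length
  rule is strict ("longer than 8"), so an 8-mer never groups.
* Empty inputs propagate as empty tables with the full column contract,
  not as errors, except where a required stratum is missing.

## Problem sizes

The shipped tests and the acceptance script run the default 120-gene
configuration (about 4,000 PSMs per tumor type), a 40-gene noise-free
recovery run, 200 random grouping structures of up to 12 proteins against
a brute-force oracle, 1,000 random-sequence digestion reconstructions, and
a 200-replicate Monte-Carlo check of the simulated intensity ratios. These
sizes were chosen to exercise every rule at meaningful multiplicity while
keeping a full validation run in the low minutes on one CPU; all scale
linearly via `sim_config()` if larger synthetic studies are wanted.

## Known limitations

* Semi-tryptic and non-tryptic peptides are not modeled; full tryptic
  specificity is assumed throughout.
* Attribution below the subgroup level (isoform-resolved quantification)
  is out of scope; a subgroup with members from both species yields no
  species-specific evidence and surfaces as undetermined.
* Cross-species ratios are unnormalized by construction; treat the
  dominant/similar boundary as conservative, not exact.
* The matrisome annotation is consumed as a given gene-level table; the
  package does not re-derive matrisome membership from domain annotations.
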