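---
title: "Methods: label-free phosphoproteomics quantitation and pathway inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free phosphoproteomics quantitation and pathway inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflow)
```

# The analysis model

`phosflow` analyzes label-free phosphopeptide quantitation across a panel
of cell lines measured in replicate LC-MS/MS runs. The statistical model
underneath every stage is multiplicative: an observed abundance is treated
as

\[ y_{pr} = 2^{\,\beta_p + \delta_{p,c(r)} + \varepsilon_{pr}} \cdot s_r \]

with peptide baseline \(\beta_p\), a class effect \(\delta\) for the cell
line of run \(r\), log-normal replicate noise \(\varepsilon\), and a
run-level scale bias \(s_r\) (injection amount, ionization efficiency).
All inference happens in log2-ratio space, which is why the pipeline never
substitutes zeros for missing values: a zero would be an infinitely strong
ratio, not an absent measurement.

## Internal-standard normalization and QC

A spiked β-casein phosphopeptide is measured in every run. Dividing all
abundances of a run by the standard's abundance in that run removes the
multiplicative \(s_r\) exactly (the standard's true level is constant by
construction). Triplicates are then summarized per cell line: a
(peptide, line) mean is reported when the peptide was detected in at least
`min_detected_replicates` runs (default 2 of 3 — the acquisition design
detects most peptides in all three runs, but no published inclusion rule
exists, so the weakest defensible rule is the default), and a coefficient
of variation (sample sd / mean) is attached with a quality flag at
`cv_threshold = 0.20`, the conventional 20% bound for label-free runs.
The CV flag is advisory; it does not silently drop data.

## Ratios, sentinels and regulation calls

For a comparison `test/reference`, quantifiable peptides get
\(\log_2(\bar y_\mathrm{test}/\bar y_\mathrm{ref})\). Peptides detected in
only one class carry sentinel codes (+9999 test-only, −9999
reference-only; NaN in neither) — these are biologically informative
(class-exclusive detection) but must never enter arithmetic, and the code
treats them as categorical throughout. Ratios are then log-centered per
comparison (mean by default; the centering statistic is not uniquely
determined by practice, so a median option exists) to remove any residual
global offset.

Regulation is called by the two-fold rule with closed bounds:
`up` iff ratio ≥ 1, `down` iff ratio ≤ −1 (in log2 units). Fold-change
only — no per-peptide variance test — because the triplicate design with
an internal standard puts the reliability burden on the CV QC upstream.

The concurrence filter asks for proteins with at least one site called in
the same direction in every *required* comparison while that site is
unchanged, oppositely regulated, or sentinel-coded in every *excluded*
comparison. A sentinel never supports a directional call, but it does
count as "not concurrently regulated" — a peptide lost entirely in the
excluded line is evidence of difference, not of concurrence.

## Motif classes and enrichment

Phosphosite context is the 13-residue window (±6) around the site, padded
with `_` at protein termini. Three kinase-consensus classes are assigned
by fixed precedence: proline-directed (P at +1; MAPK/CDK/GSK substrates),
basophilic (R at −3; PKA/PKC family), acidophilic (D/E at +1 or E at +3;
CK2-type). Precedence matters because dual-motif windows exist (e.g.
R-X-X-[pS]-P); proline-directed wins, and all matches remain queryable
via `motif_matches()`. The acidophilic pattern in the literature is
written with wildcards whose scope is ambiguous; the rule here — acidic
residue immediately C-terminal, or the canonical +3 glutamate — is
configurable through `motif_rules()`.

Enrichment is the iterative binomial scheme of motif-x: every
(offset, residue) pair is scored by the binomial upper-tail probability of
its foreground count given its background frequency; the most significant
pair is fixed if \(p < 10^{-10}\) and the count is ≥ 20; both sets are
restricted to matching windows and the search repeats. When a motif stops
growing it is emitted and its matches are removed from both sets, so
disjoint motifs are extracted one after another. The background defaults
to all quantified (not only regulated) windows — the natural proteome
context for the experiment. Candidate pairs whose background count is
zero are skipped rather than awarded infinite significance; with
thousands of background windows this only affects residues absent from
the data. Kinase-subset frequency vectors are compared between cell lines
by a Pearson chi-square homogeneity test on the 2×k table without
continuity correction, dropping categories with zero pooled totals.

## Pathway activity

The activity score asks whether the summed phosphorylation signature of a
pathway's member proteins discriminates two classes. Protein
representative values default to the mean over the protein's detected
phosphopeptides (keeping proteins with many peptides from dominating the
sum; a `max_abs` alternative is available). For a pathway with \(k\)
member proteins fully observed across the runs involved, the
per-replicate sums \(P_{c,r}\) are compared by a Welch-form t statistic
with sample standard deviations:

\[ a_p = \frac{\bar P_{c_1} - \bar P_{c_2}}
  {\sqrt{\rho_{c_1}^2/n_{c_1} + \rho_{c_2}^2/n_{c_2} + \epsilon}} \]

with \(n_{c_1} = n_{c_2} = 3\) under the triplicate design. The published
description of this statistic ("summed … mean … standard deviation …
t-test statistics") admits more than one algebra; the per-replicate-sum
Welch form is the most direct reading and is isolated behind
`activity_score()` so an alternative aggregation can be swapped in. The
variance floor \(\epsilon\) defaults to 0 — a degenerate zero-variance
case should surface as an error on real data — and exists for synthetic
noise-free inputs. Pathways enter the analysis only with
`min_members = 5` detected phosphoproteins; below that a t-type score on
sums of two or three proteins is dominated by single-protein noise. No
significance threshold is imposed on \(a_p\): the published criterion for
calling a pathway list "regulated" is not stated, so the package emits
ranked signed scores and leaves cutoffs to the caller.

## Pathway functional clustering

Pathway similarity is computed from the GO annotations of member
proteins: annotations are closed under is_a ancestors (roots excluded),
each pathway's term set is the union over members, and the pair is scored
by the Jaccard index, computed per namespace and averaged over the
namespaces present — preventing inflation from trivially shared
root-level terms. The supplementary similarity formula of the original
analysis is not recoverable from the available text, so the similarity
function is a pluggable strategy; a best-match-average variant over
member-protein pairs is included.

Clustering is hierarchical agglomerative average linkage. The default
distance follows the published procedure: 1 − Pearson correlation of the
two pathways' similarity-matrix *profiles*, excluding the pair's own two
columns (otherwise the unit diagonal forces spurious correlation). Direct
`1 − similarity` distance is available as a mode, because it is ambiguous
whether the "correlation threshold of 0.5" applies to raw similarity or
to profile correlation; the profile reading is the default and the choice
is recorded in the clustering result. Clusters come from cutting the
dendrogram at distance 1 − threshold; singletons are allowed. Pathways
are sorted lexicographically before agglomeration so tied merges are
deterministic and the partition is invariant to input order.

# The synthetic-data generator

`simulate_dataset()` emits the complete input bundle plus ground truth.
Its defaults encode the study design the pipeline targets: 5 cell lines
(reference `3KT` first) × 3 replicate runs; log2-normal baselines
(mean 20, sd 1.5, i.e. mid-range MS intensities); per-run scale biases
(log2 sd 0.5); replicate noise sd 0.2 in log2 units, which yields
triplicate CVs around 14%, comfortably inside the 20% QC bound reported
for this kind of acquisition; 50 planted ±2 log2 regulation effects in
the Ras-transformed line (the two-fold caller's target regime); 2%
class-exclusive peptides, fully missing in one non-reference line
(matching how single-class detections are coded, rather than simulating
a limit of detection); a motif mix of 40/20/15/25% proline-directed /
basophilic / acidophilic / other, reflecting the dominance of
proline-directed sites in such panels; 20 pathways × 10 members with one
active pathway at +1 log2; and a rooted ontology tree of depth 3,
branching 3, with pathway annotations drawn from community-specific
subtrees (2 communities by default) plus 10% noise terms.

Protein sequences are concatenations of the 13-mer site windows, so the
window re-extracted from the FASTA at the recorded site position is
exactly the designed context; window constraints are chosen so the
ground-truth class survives the classification precedence. The internal
standard is written as exactly `run_scale × 2^baseline` in every run, so
normalization cancels the run scales to machine precision — with zero
noise, downstream ratios equal the planted effects exactly, which the
test suite asserts.

What the generator does **not** emulate: peptide identification errors,
intensity-dependent (MNAR) missingness, retention-time drift, shared
peptides between proteins, correlated noise between co-eluting peptides,
and real GO topology (the tree has no multiple inheritance). Passing
tests therefore demonstrate the correctness of the analysis logic under
the declared statistical model, not robustness to every artifact of real
LC-MS/MS data.

# Numerical and testing choices

Binomial tails use `pbinom`; the test suite checks them against an
independent exact log-space summation to relative error 1e-9, including
the extreme \(p = 0.1^{200}\) corner. The chi-square homogeneity test is
checked against a first-principles oracle on random tables. The TSV
writers emit doubles with 17 significant digits so write→read round-trips
are bit-exact, which in turn makes the file-mediated pipeline
byte-identical to the in-memory one — an invariant the pipeline tests
hash-compare.

Test problem sizes are chosen to keep the default suite fast while
leaving comfortable statistical margins: parameter-recovery uses 100
seeded replicates of a 2-line, 200-peptide, 20-pathway design; the
null-calibration checks use 500–800 peptides. One subtlety: all activity
scores of a run share the same six replicate runs, so the mean score over
200 null pathways retains a common random component of order 0.1–0.2;
the null-centering check is therefore averaged over several seeds rather
than asserted on a single draw.

# Known limitations

- Multiply phosphorylated peptides are carried as single rows sharing one
  ratio; site-level resolution within such peptides is not attempted.
- Site positions are taken at face value from the input; no isoform
  coordinate mapping is performed.
- Kinase attribution is motif-class-based only. The mapping from class to
  kinase families (`kinase_families()`) is an illustrative static lookup,
  not a site-specific predictor.
- \(a_p\) is a ranking statistic; its null distribution is not calibrated
  to p-values (replicate counts of 3 would make such calibration fragile
  anyway).
- The published four-cluster pathway structure and specific association
  scores depend on database snapshots (pathway membership, GO) that are
  not redistributable; the clustering stage is validated on generator
  data with planted communities instead.
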