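---
title: "Tracing the seeding route of distant metastases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the seeding route of distant metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metroute)
```

## The inference problem

When a tumour metastasises, the distant lesion is seeded either from the
regional lymph-node disease (the *lymphatic* route) or directly from the
primary tumour, bypassing the lymph nodes (the *hematogenous* route). With
multi-region sequencing of the primary tumour, regional lymph-node lesions
and distant metastases of the same patient, the route leaves a genomic
footprint: under lymphatic seeding the metastasis shares mutations (and
subclones) with the lymph-node lesion that the primary lacks; under
hematogenous seeding it shares a private lineage with the primary instead.
`metroute` implements that inference chain end to end, plus a radiomics
classifier that predicts the route from MRI texture, and a simulator that
generates every input with known ground truth.

## Variant processing

**Detection filter.** A variant is accepted in a sample when it has at
least 5 supporting reads and a Fisher exact test between tumour
(alt, ref) and matched-normal (alt, ref) counts gives *P* < 0.05. The 2x2
orientation and two-sidedness are the standard somatic-call construction;
because other reasonable constructions exist, both are explicit,
documented arguments of `apply_detection_filter()`.

**Cross-region imputation.** Multi-region data allow "fetch-back" of
mutations confidently called in a sibling region: a cell that is not
already detected is *rescued* when it has >= 3 mutant reads at depth > 10,
marked *NA* when depth <= 10 (too shallow to decide), and *absent*
otherwise. The case depth > 10 with 1–2 mutant reads is deliberately
*absent*: only the two stated conditions rescue or void a call. Imputation
operates per patient across all of that patient's tumour samples.

**Presence matrix.** The phylogeny consumes a samples x mutations binary
matrix containing only mutations whose status is decidable in every sample
(`na_policy = "drop_variant"`); the permissive alternative
(`treat_absent`) codes NA as 0. Mutations possibly erased by loss of
heterozygosity are removed when (a) they are absent from at least one
sample and (b) an LOH segment of a lacking sample covers the locus
(`filter_loh_confounded()`); a mutation present in all samples is kept
regardless, since its evidence cannot have been erased.

Variant coordinates are 1-based inclusive (VCF convention); LOH segments
are 0-based half-open (BED convention).

## CCF, clonality and selection classes

The cancer cell fraction maps the variant allele fraction through purity
\(\rho\), total copy number \(C_t\) and multiplicity \(m\):

\[
\mathrm{CCF} \;=\; \mathrm{VAF}\cdot\frac{\rho C_t + 2(1-\rho)}{\rho\, m},
\]

clamped to [0, 1.5]. This is plumbing, not a purity/ploidy inference
engine: purity and copy number are inputs (multiplicity defaults to 1, the
diploid heterozygous baseline). The 95% interval is the Clopper–Pearson
interval of the VAF pushed through the same linear map. A variant is
*clonal* when the interval overlaps 1 (intervals entirely above 1
included), *subclonal* otherwise.

Selection classes compare donor-side and metastasis-side clonality. When
several candidate donors exist the donor label comes from the candidate
sample with the larger CCF (ties broken by sample order). The truth table:

| metastasis \\ donor | clonal    | subclonal             | absent   |
|---------------------|-----------|-----------------------|----------|
| clonal              | founding  | selected              | selected |
| subclonal           | persistent\_subclonal | persistent\_subclonal | novel |
| absent              | unselected| unselected            | (error)  |

The canonical four classes leave the metastasis-subclonal /
donor-present cell undefined; `persistent_subclonal` names it so the five
labels partition every variant present in the patient.

## Phylogeny and route classification

Distances between samples are Hamming distances between the binary rows —
the minimal choice for presence/absence characters; an all-zero germline
row is appended and used as outgroup so that "ancestral to" is
well-defined. Neighbour joining (via `ape::nj`) builds the topology; each
branch length is then re-expressed as the count of mutations carried by
exactly the clade below the branch, so the tree reads in mutation units.
NJ agglomeration ties are resolved by `ape`'s deterministic scan order
given the fixed sample ordering of the distance matrix.

Bootstrapping resamples mutation columns with replacement (as many draws
as mutations), rebuilds the rooted tree, and counts clade reproduction per
original internal node over B = 1000 replicates by default; replicate *r*
is seeded `seed + r`, so runs are reproducible and parallel-safe. For each
distant metastasis and each replicate, the walk from the metastasis leaf
stops at the nearest ancestor whose clade contains another donor-site
sample: lymph present and no primary votes lymphatic, primary present and
no lymph votes hematogenous, anything else is uninformative. The route is
the majority vote when its replicate fraction exceeds 0.75; otherwise the
metastasis is *ambiguous*. Multi-region sites generalise the single-sample
phrasing as "with >= 1 lymph sample to the exclusion of all primary
samples" (and vice versa). `leave_one_out_stability()` repeats the whole
chain with one sample removed at a time as a robustness probe.

## Subclone reconstruction

Variants are clustered in per-sample CCF space (absent variants enter with
CCF 0, which is what separates cross-sample private clones) with DBSCAN:
Euclidean distance, support radius `eps = 0.05`, one core point — i.e.
epsilon-connectivity. Clusters with more than 10 mutations become
subclones; the cluster whose per-sample median CCF exceeds 0.9 everywhere
is the founding clone, exempt from the size rule. Subclone CCFs are
medians over members normalised by the founding clone's median in the same
sample and clamped to [0, 1].

Each subclone gets an adjustable interval per sample,

\[
H = F + k\sqrt{\tfrac{1}{n}\sum_i (h_i - f_i)^2},\qquad
L = F - k\sqrt{\tfrac{1}{n}\sum_i (l_i - f_i)^2},
\]

with expansion factor *k* = 3, *L* clamped at 0 and *H* at 1.2 (tolerating
CCF > 1 noise while keeping the pigeonhole test meaningful). The
inequalities are evaluated per sample — the natural reading, since \(F\),
\(f_i\), \(h_i\), \(l_i\) are all per-sample quantities — and aggregated:
\(L_i + L_j > 1\) in any sample forces one subclone to contain the other;
\(L_i > H_j\) in any sample excludes *j* as an ancestor of *i*. Jointly
inconsistent intervals raise an error rather than a silent guess.

**Tree choice.** Candidate trees are scored by their *adjustment value*:
the total CCF mass, summed over samples and nodes, by which a sibling
group exceeds its parent (\(\sum \max(0, \sum_{child} F - F_{parent})\)) —
a concrete formalisation of "the amount CCF must be adjusted". For up to 6
non-root subclones `build_tree()` searches *all* rooted trees
satisfying the constraints, which guarantees the minimal-adjustment tree
is found; the descending-mean-F insertion search used beyond that size
cannot represent trees whose parent/child order inverts mean CCF, so
exhaustive search is preferred wherever it is affordable. All co-minimal
trees are reported rather than merged into one drawing. Robustness is a
bootstrap over member mutations within clusters (fraction of replicates
reproducing the parent map). Independently of the NJ tree,
`confirm_route()` checks for a subclone present (F >= 0.05) in a
metastasis and a lymph sample but no primary (lymphatic support), or in a
metastasis and a primary but no lymph sample (hematogenous support).

## Radiomics route predictor

Every ROI pixel whose 11 x 11 window fits inside the image contributes a
192-feature vector:

* 6 statistical features — the central grey value and raw intensity
  moments of order 1–5 ("moment" read in the statistical sense);
* 154 co-occurrence features — for each of the 7 offset vectors
  (−3,−1), (−1,0), (0,1), (0,3), (1,−1), (1,3), (2,−2), a symmetrised,
  normalised grey-level co-occurrence matrix (32 grey bins; quantisation
  over the image range) and 22 Haralick-family statistics. The offsets are
  the feature axis (7 x 22 = 154); the separately printed angle list is
  redundant given explicit offsets and is treated as descriptive;
* 32 Gabor features — mean response magnitude of a 4-wavelength
  (2.83, 5.66, 11.31, 22.63 px) x 8-orientation (pi/8 spacing) complex
  Gabor bank (bandwidth 1 octave, aspect 0.5, phase 0), kernels truncated
  to the analysis window.

Degenerate windows are well-defined: a constant window has energy 1 and
entropy/contrast 0; correlation and the maximal correlation coefficient
are set to 0 when the required variance or second eigenvalue does not
exist. Per-window vectors are averaged over the ROI (and over slices) to
one vector per patient.

Classification is a 1-nearest-neighbour under correlation distance
\(d(a,b) = 1 - r_{Pearson}(a,b)\), with per-feature z-scoring on the
training fold; zero-variance features are dropped with a warning.
Accuracy is estimated by leave-one-out cross-validation. `rfe_rank()`
wraps backwards elimination around this classifier (each step removes the
feature whose removal maximises LOOCV accuracy, ties broken by removing
the highest-index feature) and returns the accuracy-vs-size curve; the
final model may keep all features when no subset outperforms them.

A statistical caveat the tests account for: 1-NN LOOCV is pessimistic
under the exchangeable null, because removing the test point leaves its
own class one member short — with 8:5 classes the exact null expectation
is \((8\cdot7 + 5\cdot4)/(13\cdot12) = 0.487\), not 0.5. The null check
therefore allows exactly this finite-sample offset around the binomial
band.

## The simulator and what it does (not) show

`simulate_patient()` draws a clone tree whose site occupancy encodes the
route: the seeding clone is present in the lymph node and metastasis but
in no primary sample (lymphatic) or in the primary and metastasis but not
the lymph node (hematogenous); a metastasis-private clone descends from
it. Clone fractions are drawn by stick-breaking down the tree, so the sum
rule (children never exceed their parent) holds by construction. Default
study conditions: 5 clones, 30 mutations per clone, Poisson depth with
mean 150, purity 0.8, CCF jitter 0.02, two primary regions plus one lymph
node and one metastasis sample, binomial read counts (a beta-binomial
switch exists for overdispersion stress tests), matched normals with zero
alt reads.

Two generator choices deserve their rationale:

* **Stick range (0.65, 0.85).** A child then occupies most of its parent,
  so parent + child exceed one cell-fraction unit in some sample and the
  pigeonhole inequality *forces* the true nesting. With small child
  fractions a nested and a parallel placement are both adjustment-0
  co-minimal trees — the data simply do not determine the topology, and
  no reconstruction method could recover it.
* **The metastatic sweep.** The seeding clone reaches fixation (CCF 1) in
  the metastasis. This is what produces "selected" variants — clonal in
  the metastasis yet subclonal in the donor — without it, that class
  cannot exist in the simulation.

What the simulator does *not* emulate: mutational signatures and
trinucleotide context, copy-number evolution (copy number is fixed at 2,
multiplicity 1), contamination of matched normals, sequencing artefacts
beyond binomial/beta-binomial counting noise, and region-to-region
heterogeneity within a site beyond independent fraction draws. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated generative model, not performance on real tumours.

**Problem sizes used by the test-suite and the acceptance script.** Route
recovery runs 50 patients at the default conditions with B = 200 bootstrap
replicates (the B = 1000 default is a per-analysis knob; 200 replicates
resolve a 0.75 cutoff comfortably). The clustering oracle uses 200 random
configurations of up to 100 variants in up to 4 samples; the tree-choice
oracle enumerates all rooted trees for up to 5 non-root subclones; the
interval oracle evaluates 1000 random subclones. The radiomics null runs
200 (tests) or 100 (script) cohorts of 13 tiny textured images in the
study's 8:5 class mix.

**Cluster density matters for DBSCAN.** With a support radius of 0.05 and
one core point, clustering is epsilon-chaining, and a cluster survives
only if member CCFs sit within 0.05 of a neighbour. The per-variant CCF
noise after the purity map is roughly
\(2.5\sqrt{\mathrm{VAF}(1-\mathrm{VAF})/\mathrm{depth}}\) — about 0.09 at
depth 150 for a mid-range VAF, which fragments 30-mutation clusters; at
depth 400 (noise ~ 0.055) recovery is reliable. The subclone
parameter-recovery test therefore runs at depth 400, and users clustering
sparse, shallow data should expect fragmentation rather than silent
merging (the retention rule discards fragments of <= 10 mutations).

## Numerical and degenerate-input conventions

* Clopper–Pearson bounds via `qbeta`; `alt = 0` gives lower bound 0,
  `alt = depth` upper bound 1; depth 0 is an absent call with undefined CCF.
* CCF clamp 1.5 before the clonality call; interval clamps L >= 0, H <= 1.2.
* Identical presence rows yield zero-length sister branches; a trunk-only
  matrix yields a star with the trunk carrying all mutations.
* GLCM entropies use log2; sums over empty cells are skipped exactly.
* All bootstraps derive replicate *r*'s seed as `seed + r`; simulator
  cohorts use `master seed + patient index`. Fixed seeds give bitwise
  identical outputs everywhere.
* Newick output escapes spaces per the underscore convention and stores
  bootstrap supports as internal node labels.

## Known limitations

* The CCF estimator is intentionally simple; it does not infer purity,
  ploidy or multiplicity and will mislabel clonality when those inputs are
  wrong.
* Route classification needs at least one pre-treatment sample of each
  site; patients missing a site get the subclone-level
  `confirm_route()` evidence only.
* The exhaustive tree search is exponential; beyond 6 non-root subclones
  the insertion search is a heuristic and co-minimality is then relative
  to its search space.
* The radiomics arm operates on plain 2-D arrays with masks; DICOM
  handling, registration and segmentation are out of scope.
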