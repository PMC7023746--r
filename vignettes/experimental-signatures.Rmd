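---
title: "Detecting experimentally generated mutational signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting experimentally generated mutational signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsigexp)
```

## The experimental model

`mutsigexp` analyses whole-genome sequencing data from subcloning experiments
in cellular model systems. The genealogy is: a **grandparental** clone (the
isogenic genetic reference), **parental** clones that underwent a manipulation
(a gene edit, or a genotoxin exposure with recovery), and — after a mutation
accumulation phase — multiple single-cell **subclones** per parent, sequenced
in bulk. The single-cell bottleneck is what renders each cell's private
mutations clonal and hence detectable: in a clonal subclone, a de novo
heterozygous mutation is carried by every cell, so the fraction of reads
showing it (the VAF) scatters around `mutated_copies / ploidy` — 0.5 in a
diploid, 1 in a haploid, about 0.33 for a single copy in a triploid.

The package's central statistical assumption is the **linear-combination
model**: the mutational profile of an experimental subclone is a mixture of the
background (intrinsic and culture-associated) mutagenesis of the cellular
system and the mutagenesis attributable to the manipulation. The background is
estimated from control subclones — their averaged burden and averaged
normalised profile — and everything downstream (burden testing, SNR,
subtraction) is a comparison of treated subclones against that control-derived
background. Control subclones of the same lineage act as technical replicates,
which is why the package weights subclones equally (profiles are normalised
per subclone before averaging) rather than pooling raw counts: a
high-burden subclone should not dominate the centroid.

## Channel schemes

Each mutation class has its own channel set; the ratio of mutations to channels
matters, because too many channels dilute a low-yield signal and too few lose
resolution:

* **SBS-96**: 6 pyrimidine substitution classes x 16 trinucleotide contexts.
  Classification is strand-agnostic: purine-reference calls are
  reverse-complemented together with their context (swapping the flanks).
* **DBS-78**: the 144 ordered ref>alt dinucleotide pairs collapse to 78
  strand-agnostic channels. The canonical orientation is the lexicographically
  smaller reference dinucleotide, ties (reverse-complement-palindromic
  references) broken by the smaller alternate. Any fixed total order
  reproduces the same 78-label set; lexicographic is simply deterministic and
  auditable. A flank-extended scheme (4 x 78 x 4 = 1248 channels) is provided
  but rarely appropriate: typical doublet yields are far too low for 1248
  channels. In the flanked scheme the flanks are reported relative to the
  canonical orientation of the inner doublet only, which is what makes the
  label count exactly 4 x 78 x 4.
* **Indels (34 channels)**: class (`ins`/`del`) x size/content
  (`1bp_C/G`, `1bp_T/A`, `longer`) x junction mechanism. The mechanism is
  `rep_N` when the indel motif has perfect adjacent copies in the reference
  (for deletions the count includes the deleted copy and needs at least 2; for
  insertions one adjacent reference copy suffices; counts cap at `5+`), `mh`
  for deletions of 2 bp or more with at least 1 bp of junction microhomology
  and no repeat, else `none`. Published indel schemes vary in repeat-bin
  granularity; this compact default reflects the modest indel yields of
  experimental systems and the scheme is a constructor, so alternative
  granularities can be built without touching the classifiers.
* **Rearrangements (16 channels)**: tandem duplications, deletions and
  inversions in five log-spaced size bins (<10 kb, 10–100 kb, 100 kb–1 Mb,
  1–10 Mb, >10 Mb) plus translocations, which carry no size. Five log bins
  span the biologically distinct regimes (small tandem events through
  chromosome-arm scale) without over-splitting the low counts typical of
  experiments.

Comparisons with cancer-derived signatures go through `collapse_signature()`:
the finer cancer signature is pooled onto the experimental channels (weight is
conserved channel by channel). The package deliberately does **not** fit
a-priori signatures to experimental catalogs: a fitting algorithm will report
whatever it is offered, whether or not the process is present in the sample.

## Quality control

Three failure modes dominate in practice, and each has a signature in the data:

* **Polyclonal or mosaic subclones** show depressed mean VAFs and falsely
  elevated burdens (subclonal mutations still get counted). The clonality rule
  is deliberately two-part: a one-sided test that the mean VAF lies below the
  ploidy expectation at `alpha = 0.001` **and** an effect-size floor
  (observed mean below `0.8 x` expectation). The floor exists because deep
  sequencing makes trivially small deviations significant; without it a
  perfectly usable subclone sequenced at depth 1000 would be flagged. Fewer
  than 20 usable VAFs is reported as *inconclusive*, never as a verdict.
  A polyclonality flag marks the quantitative burden as unreliable; the
  mutational profile itself is usually unaffected, so flagged subclones can
  still inform the qualitative spectrum.
* **Mislabelled or wrongly sequenced parents** are exposed by shared-variant
  counts: every subclone must contain (nearly) all of its parent's mutations
  and at least one private mutation. The containment threshold
  `theta_p = 0.9` tolerates a few percent of variant-calling dropout while
  cleanly separating a true parent (containment ~1) from an unrelated clone
  (containment ~0).
* **Mixed parental populations** split the declared siblings into groups:
  single-linkage clustering of the pairwise shared-fraction (shared count over
  the smaller burden) cut at `theta_s = 0.5` finds them. At realistic burdens
  (parental >= 50), within-lineage sibling pairs share well above half of the
  smaller burden and cross-lineage pairs essentially nothing, so the verdicts
  are insensitive to the exact cut; both thresholds are nonetheless arguments,
  not constants.

The decision order is: all subclones contained and private -> *consistent*;
otherwise two or more sibling clusters -> *mixed parental*; otherwise ->
*wrong parent*. Copy-number stability and driver screening are reported as
*not assessed* — they require CNV calls and annotation databases outside this
package's scope.

## Burden test

The quantitative question — do treated subclones carry more mutations than
controls? — is answered with a seeded resampling test
(`burden_test()`). The reported p-value comes from a **group-label permutation
test** of the difference in mean burden, with the add-one correction
(`p >= 1/(n_boot + 1)`), one-sided for excess by default. The bootstrap
distribution of control means (resampling the control burdens with replacement
at the control group size) is computed alongside and reported as the expected
null summary, which is the natural display of "what burdens would controls
produce".

The reason the permutation test supplies the p-value, rather than ranking the
experimental mean within the bootstrap distribution directly, is calibration:
the bootstrap-of-control-means distribution captures only the variability of
the *control* mean, so ranking the experimental mean inside it ignores the
sampling variability of the experimental group entirely and rejects far too
often at small, equal group sizes (analytically ~5–10% at nominal 1%). The
permutation test is exactly calibrated at any group size. The bootstrap
ranking remains available as `method = "bootstrap"` for comparability.

One practical consequence of permutation granularity: with `n_c` controls and
`n_e` treated subclones there are `choose(n_c + n_e, n_e)` distinct
label assignments, so the smallest achievable p-value is about its inverse.
Reaching `p <= 0.01` needs, e.g., six controls and six treated subclones
(924 splits); with three per group (20 splits) no burden difference can clear
the cutoff. This is a property of the design, not the software, and is worth
knowing when choosing replicate numbers. The package's calibration suite
accordingly uses six control and six experimental subclones per replicate with
Poisson(200) burdens — group sizes at which both the test and the cutoff are
meaningful.

When several conditions are tested at once, raw p-values are accompanied by
Benjamini–Hochberg adjusted ones (`condition_burden_tests()`).

## Signal-to-noise ratio

The qualitative question — do the treated *spectra* differ? — is summarised by

`SNR = ||mu_Exp - mu_Control||_2 / sqrt(||sigma_Control||_2^2 + ||sigma_Exp||_2^2)`

where `mu` and `sigma` are the per-channel mean and standard deviation of the
normalised profiles within each group. The numerator is the Euclidean distance
between group mean profiles (the signal); the denominator aggregates the two
groups' per-channel SDs in quadrature, treating the group noises as
independent — this is this package's reading of "variability of mutation
profiles among subclones", and it is stated prominently because other readings
exist; `noise_method = "mean_sd"` (the mean per-channel SD) is provided as an
alternative. SDs are population SDs by default (divide by n): the quantity is
a descriptive spread of the observed replicates, not an estimator of a larger
population; `sd_type = "sample"` switches to n−1. Degenerate cases are
defined, not propagated: zero noise with non-zero signal is flagged infinite,
and 0/0 is 0.

## Background subtraction

`subtract_background()` extracts the experiment-associated signature:

1. **Centroid**: mean experimental burden x mean normalised profile, as
   expected counts per channel.
2. **Bootstrap**: each subclone's counts are redrawn from its own multinomial
   `n_boot` times; per replicate the redraws are averaged into a replicate
   centroid (averaging replicates across subclones, then taking percentiles —
   the alternative order is a one-line change but this is the default). The
   0.5 and 99.5 percentiles give the per-channel 99% CI of mutation numbers.
   The background is bootstrapped alongside: multinomial redraws at the
   background burden from the background profile. The per-channel tolerance
   `w_c` is the bootstrap mean minus the lower CI bound of the replicate
   *residuals* (centroid minus bootstrapped background) — how far below its
   expectation a channel can fall from resampling noise alone. Using the
   experimental spread only would set `w_c = 0` on any channel the finite
   sample happened to miss while the background still has support there,
   forcing the scale to zero; including the background's own resampling noise
   is what makes the rule behave.
3. **Scale**: the background counts `B x beta` are scaled by the largest
   `alpha* <= 1` with `centroid_c - alpha* B beta_c >= -w_c` on every channel:
   `alpha* = min(1, min_c (centroid_c + w_c) / (B beta_c))` over channels with
   background support. This closed form is the deterministic,
   order-independent realisation of "reduce the background burden when
   subtraction pushes channels below their CI"; it reduces to plain
   subtraction (`alpha* = 1`) exactly when all negativity is within CI noise.
   `alpha*` effectively vanishing (<= 1e-6) is a *degenerate subtraction*
   error: the background saturates the signal.
4. **Clamp and normalise**: residuals still negative at `alpha*` (all within
   tolerance by construction) are zeroed and recorded; the clamped residuals
   normalised are the signature, their sum the attributed burden. If
   everything clamps to zero the signature is explicitly empty with attributed
   burden 0.

CIs are computed on **counts**, not proportions, because the object of
interest is the distribution of mutation numbers per channel. Bootstrap
quantiles use R's default (type 7) interpolation; on count distributions the
difference from discrete quantiles is below one mutation and is covered by the
tolerances used in tests.

Stability: `per_subclone_signatures()` re-runs the subtraction on each treated
subclone alone and `stability_report()` summarises all pairwise cosine
similarities, flagging the extraction stable when the minimum exceeds 0.9.
Cosine similarity is reported with its caveats: it is most informative for
peaked signatures, it is not linear (0.8 is not "high"), and identical
signatures do not imply identical mechanisms.

## The synthetic-data generator

`simulate_experiment()` generates data with exactly the statistical structure
the framework assumes, so the pipeline can be exercised and its operating
characteristics measured without any external data. It emulates:

* genealogical sharing — parents carry `parental_burden` background mutations
  inherited by all their subclones; each subclone adds `private_burden`
  private background draws, and treated subclones add `treatment_burden` draws
  from the treatment signature (the linear-combination model made literal);
* channel-faithful placement — channel counts are multinomial draws from the
  signature, each mutation placed at a uniformly chosen reference locus whose
  trinucleotide context matches its channel, so re-classification reproduces
  the drawn counts exactly;
* read sampling — VAFs are `Binomial(depth, expected_vaf) / depth`, binomial
  read noise only;
* planted QC defects — a wrongly sequenced parent, a mixed parental population
  (with six subclones, groups 1/4/6 versus 2/3/5), or a polyclonal subclone
  (half of its de novo mutations at half the clonal cell fraction, hence half
  the expected VAF).

Defaults are chosen as realistic study conditions for a diploid model at 30x
depth: 2 parents (1 control, 1 treated lineage), 4 subclones per parent, 200
shared parental mutations, 150 private mutations per subclone — burdens in the
range cell-culture backgrounds produce — and a peaked, C>A-heavy default
background profile, the oxidative-stress-like pattern characteristic of cells
in culture. All loci are unique within an experiment (experimental burdens are
minuscule against a genome, so recurrent hits are not modelled; colliding
draws are simply avoided).

What the generator does **not** emulate — and therefore what passing tests do
not certify about real data: sequencing and alignment artefacts, variant
caller false positives/negatives, copy-number changes and their effect on
VAFs, contamination and purity, mutation-rate heterogeneity along the genome,
selection during culture, and whole-genome-amplification artefacts of
single-cell protocols. The generator validates the *statistical machinery*
under its stated assumptions, not the upstream calling pipeline.

Test and simulation sizes used by the package's own suites (chosen to make the
statistical claims sharp at interactive runtimes): references of 30–300 kb,
burden-test calibration on 1000 null replicates at `n_boot = 2000`,
signature-recovery at 4 subclones x (200 background + 600 treatment) over 20
seeds, and 100 seeded replicates per QC scenario.

## Reproducibility

Every stochastic operation takes an explicit integer seed, records it (and
`n_boot`) in its result, and is bit-for-bit reproducible given them. RNG use
is locally scoped (`withr::with_seed`), so calling package functions never
perturbs the caller's RNG stream. CLI runs write a `.run.json` record of
parameters, seeds and versions next to each output.

## Known limitations

* Single-signature subtraction only: one background plus one
  experiment-associated signature, per the linear-combination model. De novo
  multi-signature decomposition (NMF) is intentionally out of scope.
* The burden test compares means; with very few replicates its permutation
  granularity bounds the achievable p-value (see above).
* Indel and rearrangement simulation are not generated by
  `simulate_experiment()` (classification and cataloguing of those classes are
  fully supported from VCF/BEDPE input).
* The clonality test assumes a single ploidy state across the genome; loci
  with copy-number change violate the expected-VAF model.
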