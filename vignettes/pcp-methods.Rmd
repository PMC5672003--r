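---
title: "Deconvolving SEC co-fractionation profiles into oligomerization calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving SEC co-fractionation profiles into oligomerization calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpfit)
```

## The measurement and the model

Protein correlation profiling infers the native state of a protein from
how its abundance co-varies across biochemical fractions.  Here the
separation is size-exclusion chromatography (SEC) of cholate-solubilized
microsomal (membrane-derived) proteins: a complex elutes earlier than its
free subunit, so the elution position carries the apparent native mass.
Each protein contributes, per biological replicate, a vector of raw XIC
intensities over the collected fractions (24 for the Superdex-type scheme
used throughout, with the void at fraction 2).

A profile frequently holds more than one peak — a protein can exist in
several oligomeric states at once — so the core model is a sum of `K`
Gaussian components on the fraction axis,

$$ I(f) \;=\; \sum_{k=1}^{K} A_k \exp\!\Big( -\frac{(f-\mu_k)^2}{2\sigma_k^2} \Big), \qquad K \le 4, $$

fitted by bounded nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`).  `fit_elution_peaks()` is the fitting function; it returns a
classed object with the usual `print`, `coef`, `predict`, `fitted`,
`residuals` and `plot` methods.

### Acceptance rules and model selection

Three rules keep the deconvolution conservative:

* **Eligibility.** A protein must be quantified in at least three
  fractions, two of them adjacent; anything sparser has no usable shape.
* **Separation.** Retained peaks must be at least 4 fractions apart —
  roughly the resolution of the column.  Candidate models violating this
  are discarded, which is how two true peaks closer than 4 fractions
  collapse into one reported peak.
* **Relative height.** Every non-maximal peak must reach 20% of the most
  intense peak.  Weaker components are pruned and the model is refit with
  fewer components until the rule holds (simple removal without refitting
  would leave the surviving amplitudes biased).

The number of components is chosen by the lowest BIC,
`n ln(RSS/n) + 3K ln(n)`, with three free parameters per peak and an RSS
floor of `1e-10` guarding the noiseless case.  Both rules are applied as
post-fit accept/prune steps rather than as optimizer constraints, keeping
the least-squares problem smooth.

### Numerical choices

Component centers are seeded at local maxima of the 3-point
moving-average smoothed profile, ranked by height; at most as many
components are attempted as the profile has local maxima.  Widths start at
1.5 fractions and are bounded to [0.5, 5]; centers to one fraction beyond
the grid; amplitudes to twice the observed maximum.  The fit is fully
deterministic — no random restarts — so a given profile always yields the
same model.

Isolated interior zeros (a zero flanked by two quantified fractions) are
treated as XIC dropout — the peptide was simply not picked in that run —
and imputed from the neighbor mean before fitting (`impute_dropouts()`).
Zeros at profile edges and runs of two or more zeros are kept as genuine
below-detection values.  Without this, a single dropped fraction inside a
peak drags the least-squares center by half a fraction or more.

Profiles that cannot be fitted fall back to the global maximum (integer
fraction, earliest on ties, tie recorded); all-zero profiles are marked
ineligible.  Void-region fractions are included in the fit; peaks landing
there are flagged unresolved rather than masked, so a genuine void peak
can coexist with a resolved peak in the same model.

## From peaks to masses and oligomerization calls

Reproducibility across the two biological replicates is required before
any interpretation: peaks are matched one-to-one, greedily by smallest
center shift, and accepted when the shift is at most 2 fractions
(inclusive — the threshold and its inclusivity are exposed in
`pipeline_config()` because "two fractions" can reasonably be read either
way).  Because retained peaks within a replicate are at least 4 fractions
apart while the tolerance is 2, at most one partner can lie within
tolerance and the greedy matching coincides with the exhaustive optimal
assignment — a property the test suite verifies against a brute-force
oracle.  Reproducible peaks are labelled P1, P2, ... in decreasing
apparent mass.

The calibration model is ordinary least squares of `log10(mass)` on the
peak fraction of the 29–669 kDa sizing standards (the void standard is
excluded).  A peak is resolved when its center is at least one fraction
past the void (inclusive); only resolved peaks receive masses.  The
per-peak summary mass is the geometric mean of the two replicate masses,
since mass is log-linear in elution position.  Superdex and Superose runs
get independent calibrations; their per-column resolving limits (~900 kDa
and ~5 MDa) decide which column's mass is quotable for a given peak.

The oligomerization ratio is `R_app = M_app / M_mono` with the monomer
mass taken from the sequence annotation.  Classes are boundary-inclusive:
degraded below 0.5, monomer [0.5, 2), small complex [2, 10), large
complex at and above 10.  A protein is *predicted as a complex* when the
peak is reproducible and `R_app >= 2` in at least one replicate — the
per-replicate evaluation matters, so both replicate ratios are kept
alongside the geometric-mean ratio used for the class label.

## Membrane filtering and dual localization

Sucrose velocity gradient profiles separate membrane vesicles (which
sediment deep) from soluble contaminants (top fractions).  The same
deconvolution machinery runs on the sucrose tables; a protein's dominant
reproducible peak counts as deep when its center lies strictly beyond
fraction 8.  A cholate-detected protein is called membrane-associated
when it is absent from the cytosolic dataset, or present there but with a
deep sucrose peak; otherwise it is a cytosolic contaminant.  We use the
dominant (highest-amplitude) reproducible peak for this decision; which
peak the original rule referred to is not decidable from the wording, and
the dominant peak is the conservative reading.

For dual-localized proteins the ratio of cytosolic to membrane apparent
mass flags a change of oligomeric state between compartments (ratio above
2 or below 0.5).  Cytosolic species at or above 450 kDa are excluded from
this comparison: their gradient mobility cannot be distinguished from
vesicle sedimentation.  Cytosolic apparent masses come from an external
soluble-fraction table and are never recomputed here.

## Reference complex coverage

Known metazoan complexes are projected onto the target species through
ortholog maps (any mapping source counts; one-to-many mappings are all
retained and their multiplicity recorded).  Complexes from different
source species with identical mapped subunit sets collapse to one record.
Coverage is high at 80% of subunits (or the 3-of-4 / 2-of-3 small-complex
cases), medium from 60%, low from 40%.  The assembled mass `M_calc` is
the plain sum of subunit monomer masses — unit stoichiometry is a known
limitation — and the target-species `M_calc` is reported only at 100%
ortholog coverage.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the full input bundle (SEC and sucrose
quantification tables for two replicates, standards, annotations, a
cytosolic mass table) with ground truth attached.  Its defaults define
the study conditions used throughout the tests:

* 24 SEC fractions, void at 2; 25 sucrose fractions; 1–4 Gaussian peaks
  per protein with probabilities 0.75/0.20/0.04/0.01, widths 1–2.5
  fractions, log-normal amplitudes;
* replicate jitter: normal with SD 0.5 fractions, truncated at ±2;
* multiplicative log-normal noise (CV 20% by default), a small additive
  floor, 2% per-fraction dropout, detection floor at 1% of the profile
  maximum;
* oligomer states in equal proportions with true `R_app` of 0.3 / 1 / 4 /
  12 (degraded / monomer / small / large), encoded by deriving each
  protein's monomer mass from its dominant peak position through the
  noiseless calibration law (standards 29–669 kDa, slope −0.105 log10
  kDa per fraction);
* a 5% void-trapped subpopulation, a 20% cytosolic-contaminant
  subpopulation whose sucrose peaks sit in fractions 2–7.5 (10% of them
  with a deep bleed-through component), and 10% single-peptide
  identifications straddling the score-5 acceptance rule.

The generator does **not** emulate peptide-level quantification noise
structure, retention-time alignment artifacts, shared-peptide (razor)
ambiguity, correlated noise between adjacent fractions, or non-Gaussian
peak shapes (tailing).  Passing the recovery benchmarks therefore shows
that the deconvolution, matching and classification logic is correct
under the stated noise model — not that real co-fractionation data meets
these error rates.

Benchmark problem sizes were chosen so the whole suite runs comfortably
on a laptop: 500 proteins for the peak-recovery benchmark (SNR 10,
separation ≥ 6, secondary heights ≥ 40%) and 300 proteins for the
end-to-end state-recovery benchmark; both complete in seconds.

## Degenerate inputs and tie-breaks

All-zero profiles are ineligible; profiles failing the eligibility rule
use the global maximum; global-max ties take the earlier fraction and are
recorded.  Matching ties (equal shifts) are broken by replicate-1 peak
order, which keeps the matching symmetric in practice.  An `RSS` of zero
in the BIC is floored; sucrose schemes have no void, so every sucrose
peak is resolved by construction.  Empty tables propagate as empty result
tables, never as errors.

## Known limitations

* Gaussian peak shape only; strongly tailing peaks bias centers.
* Unit stoichiometry in `M_calc` understates complexes with repeated
  subunits.
* Cross-column (Superdex vs Superose) peak matching is out of scope; each
  column is analyzed independently.
* The membrane filter inherits any bias of the external cytosolic table.
* `R_app` conflates shape and glycosylation effects with oligomerization;
  a ratio near 2 is not evidence of a homodimer.
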