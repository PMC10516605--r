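---
title: "Methods: MSI scoring and frameshift calling in mononucleotide-repeat amplicons"
author: "msifsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI scoring and frameshift calling in mononucleotide-repeat amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msifsm)
```

## The problem

Tumours deficient in DNA mismatch repair (MMRd) fail to correct
replication-slippage errors, so indels accumulate in microsatellites —
above all in mononucleotide repeats (MNRs), where a single-unit deletion in
a coding tract produces a frameshift mutation (FSM) and, downstream, a
frameshift peptide neoantigen. Two laboratory readouts are standard:

1. **Targeted amplicon sequencing** of coding MNR hotspots, calling somatic
   −1 bp frameshifts from read counts; and
2. **Fragment analysis**: capillary-electrophoresis sizing of fluorescent
   PCR products over a panel of MNR markers, classifying a sample MSI-high
   (MSI-H) when two or more markers are unstable.

Both are confounded by the same artifact that makes microsatellites
mutable in the first place: *PCR stutter*. Polymerase slippage during
amplification produces reads (and electrophoretic peaks) offset by one or
more repeat units from the template allele, even in wild-type DNA. Any
caller must therefore separate true somatic indels from this background.

`msifsm` implements the full desk-side pipeline — a seeded stutter
simulator, read processing, a Weibull background-error test, fragment-trace
MSI scoring, and a read-frequency hotspot caller — so every stage can be
exercised and audited without external data.

## Read processing

Amplicon reads are single-end and span the whole product, so no genome
alignment is needed. `trim_and_assign()` matches each read prefix against
every forward primer in the panel (default budget: 2 mismatches in a 20-mer)
and assigns the read to the unique matching locus; ambiguous or unmatched
reads are set aside with the reason recorded. `extract_repeat_count()` then
anchors the 6 bp of flank on either side of the repeat tract and requires
the spanned sequence to be a *pure* repeat run with a whole number of units.
Reads failing anchoring or purity are excluded rather than rescued: with a
known amplicon structure, anchoring is deterministic and sufficient, and it
keeps the observed repeat length unambiguous (panels are validated so that
flanks never extend the repeat run and left anchors occur uniquely in their
flank).

`tabulate_indels()` reduces observations to one row per
(sample, locus, offset ≠ 0), with

\[ \mathrm{VAF} = \frac{\text{mutant reads}}{\text{mutant reads} + \text{WT reads}}, \]

using the mutant-vs-WT denominator rather than all usable reads (the
alternative changes VAFs by at most the summed minor-offset mass; the
chosen form matches how mutant and wild-type read counts are reported in
this assay family). Offsets are zero-filled across samples so that
wild-type controls contribute explicit 0-VAF rows at tumour-only offsets.

## The Weibull background-error model

For each indel (locus–offset pair) the VAFs of the wild-type control
samples are fitted to a two-parameter Weibull distribution. The Weibull is
a natural choice for this background: it lives on \(x > 0\), is
right-skewed for shapes \(k < 3.6\), and with two parameters adapts to the
very different stutter intensities of short coding tracts and long
markers. Zero VAFs (controls with no mutant read) are replaced by a floor
\(\varepsilon = 1/(2\,\tilde d)\), half a read at the median control depth
\(\tilde d\), before fitting; a censored-likelihood treatment of zeros is
noted as future work.

The fit is maximum likelihood: the shape solves the profile equation

\[ \frac{1}{k} + \overline{\log x} - \frac{\sum x_i^k \log x_i}{\sum x_i^k} = 0 \]

by Newton iteration (tolerance \(10^{-8}\), bisection fallback; the
equation is monotone so the root is unique), and the scale is
\(\hat\lambda = (\overline{x^{\hat k}})^{1/\hat k}\). The shape is capped
at \(k_{\max} = 50\); a capped or all-equal fit is flagged *degenerate* and
never used for testing — a near-vertical survival curve would otherwise
call any VAF a hair above the floor positive on the strength of a single
stray stutter read. Degenerate or under-powered indels (fewer than 5
controls) instead fall back to an exact one-sided binomial test of the
mutant read count against \(p_0 = \max(\varepsilon, \text{mean control
VAF})\).

A tumour sample's VAF is then scored one-sided against the fitted
background,

\[ p = \exp\!\left[ -\left( \frac{\max(\mathrm{VAF}, \varepsilon)}{\hat\lambda} \right)^{\hat k} \right], \]

the Weibull survival probability ("significantly above background" is
directional, hence an upper tail). All tumour-sample × indel tests of a run
are pooled into a single Benjamini–Hochberg batch — the conservative,
reproducible reading of "FDR correction"; per-sample batching is available
behind a flag — and a sample is positive when \(q < \alpha\) with
\(\alpha = 0.05\) on the *adjusted* value (the raw-p reading is available
via `threshold = "raw"`). Wild-type controls are never tested against the
background they defined; leave-one-out refitting is off by default.

### A measured limitation: plug-in p-values with few controls

The p-value above plugs the point estimates \((\hat k, \hat\lambda)\) into
the survival function and ignores their sampling error. Because
\(\hat k / k\) is a pivotal quantity, the resulting miscalibration depends
only on the number of controls, not on the true parameters: with the
default 8 controls the realised type-I error at nominal \(p < 0.05\) is
about 0.08 (reported as `allnull_raw_type1_rate` by
`scripts/acceptance.R`, which recomputes it from all-null cohorts at run
time), and across the hundreds of tests of a cohort the smallest null
p-values essentially always clear the BH threshold, so occasional false
positives at the tested offsets are expected. The effect shrinks roughly
as \(1/n\) in the control count and is negligible by \(n \approx 200\).
Callers needing strict calibration at small \(n\) should treat borderline
calls accordingly; accounting for estimation uncertainty (e.g. a
parametric-bootstrap predictive p-value) is deliberately out of scope here
because the plug-in form *is* the method under study.

## Fragment-analysis MSI scoring

Traces enter as (size, intensity) tables on a 1-bp grid.
`detect_peaks()` keeps local maxima at or above 10% of the trace maximum
(the typical fragment-analysis analytic threshold), thinned to a minimum
2 bp separation, taller-first with ties broken toward the smaller size.
`score_marker()` declares a marker unstable when

* the sample's **dominant** (tallest) peak is shifted by ≥ 1 bp from the
  control's dominant peak — the shift magnitude in bp is reported as the
  "mN" value (m4 = 4 bp shift) — **or**
* the sample shows **new peaks** with no control peak within
  `tolerance_bp` (0 on the simulator's integer grid; set 1 for real,
  noisier traces).

The dominant-peak reading of "1-bp shift" was chosen over an any-peak
reading for determinism; ties break toward smaller sizes because slippage
in MMRd tumours is deletion-biased. Minor peaks within 2 bp *below* a
taller sample peak and under 50% of its height are treated as the stutter
ladder and never count as new peaks (configurable; the published scoring
rules do not state a stutter-exclusion criterion, so this reconstruction is
flag-controlled). `classify_msi()` applies the panel rule: MSI-H with ≥ 2
unstable markers, MSS with ≤ 1; fewer than 2 evaluable markers is
unevaluable. `compare_profiles()` differences two mN profiles and flags
increased instability when the median per-marker delta is positive.

## The hotspot caller

For hotspot amplicons (a Trp53-style assay), `top_common_reads()` ranks the
distinct read sequences of a sample by copy number (ties lexicographic) and
keeps the top K = 300 (the upper end of the customary 100–300 window);
frequencies are always computed over *all* assigned reads, so K only limits
discovery, not quantification — an edit carried solely by reads below rank
K is undiscoverable by construction. Each kept read is globally aligned to
the reference (unit mismatch/gap costs; global, because amplicon reads span
the reference — a local mode exists for truncated reads), and every indel
is normalised to its leftmost equivalent placement so that the same
homopolymer indel from different reads aggregates under one key. Edits are
pooled across reads and reported when their summed read frequency strictly
exceeds 4%.

## The synthetic-data generator

The generator is the package's study population; its defaults were fixed
once, on realism grounds, and define the conditions under which the test
suite runs:

* **Stutter**: a read's observed repeat length slips with probability
  `stutter_rate = 0.02`; slip sign is equiprobable and magnitude \(m\) has
  \(P(m) \propto 0.3^{\,m-1}\) (`stutter_decay = 0.3`) — the simplest model
  producing the dominant ±1-unit artifact structure the Weibull background
  must absorb, applied identically to wild-type and mutant template reads.
  This puts the mean −1 background VAF near 0.7%, inside the 0.5–2% window
  a targeted MNR assay typically shows.
* **Substitution errors** at `1e-3` per base, uniform, never inside the
  6 bp anchor windows (a stated simplification that decouples anchor
  integrity from error handling; errors inside the tract still occur and
  such reads are dropped by the purity check).
* **Reads** are single-end, span the full amplicon, and carry constant
  quality; no PCR-cycle-explicit chemistry, no paired ends, no
  quality-dependent error model.
* **Traces** are ideal stutter ladders (each allele contributes
  \(f \cdot r \cdot d^{\,k-1}\) at ±k bp) plus half-normal baseline noise
  of scale `noise_sd` (2% of a full-height peak by default).
* **Cohorts**: the bundled demonstration cohort uses 10 organoid-like,
  18 end-stage-tumour-like and 16 mucosa-like samples against 8 wild-type
  controls at depth 2000× per locus, with −1 frameshifts planted at five
  coding loci at per-sample VAFs drawn once from U(0.25, 0.55). Planted
  per-group positive fractions reproduce a published cohort table *by
  construction*; fractional denominators (e.g. 1/14) are realised as
  amplicon dropout (depth-0 loci). All randomness flows from explicit
  seeds, and the whole pipeline is a pure function of its configuration.

What passing tests therefore show is that the implementation recovers what
it planted under an idealised noise model; they do not certify performance
on real data, where stutter varies with repeat length and run, depths vary
per amplicon, errors are quality-dependent, and electrophoretic sizing is
non-integer.

## Numerical and design choices

* Offsets are measured in repeat units (equal to bp for mononucleotide
  repeats); non-integral anchor spacing marks a read unusable rather than
  being rounded.
* Backgrounds are fitted per locus–offset pair, not pooled across loci:
  loci with different tract lengths have very different stutter scales, and
  pooling would be anti-conservative exactly where stutter is strongest.
  This choice is explicit and should not be changed silently.
* The Newton fit is compared in the test suite against an independent
  grid-search profile-likelihood oracle (agreement required to 1%) and
  against `fitdistrplus`.
* Thresholds are strict inequalities where the rule is worded strictly
  (`q < 0.05`, frequency `> 4%`, shift `>= 1` bp).
* Problem sizes in the test suite (200-draw fits × 50 seeds, 100 all-null
  cohorts, 50 planted cohorts, 200 trace panels, 20 000-read hotspot
  samples) were chosen so the whole suite re-derives its claims from
  scratch in a few minutes on one CPU.

## Known limitations

* The plug-in Weibull p-value is anti-conservative with few controls (see
  above); the packaged demonstration cohort, with 8 controls, exhibits
  occasional false positives at tested indels as a direct consequence.
* The new-peak rule on real traces needs `tolerance_bp = 1` and benefits
  from size-standard calibration, which is out of scope.
* No germline/somatic joint genotyping, tumour-purity modelling,
  multi-allele phasing, UMI handling, or base-quality filtering.
* ABI/FSA binary trace parsing is out of scope; traces enter as text
  tables.
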