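---
title: "Software-targeted prenatal CMA: model, parameters and design notes"
author: "targetCMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Software-targeted prenatal CMA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(targetCMA)
  library(GenomicRanges)
})
```

## The problem and the approach

Prenatal chromosomal microarray (CMA) by array CGH detects copy-number
variants (CNVs) far below karyotype resolution, but most small CNVs have an
uncertain prognosis, and reporting them to an anxious couple does harm
without clinical benefit. The strategy implemented here decouples
*diagnostic* resolution from *technical* resolution: the array is analysed
at full probe resolution, but software masks every call that is neither

* strictly larger than a **backbone threshold** (default 3 Mb), nor
* overlapping a **targeted syndrome region** — an established
  deletion/duplication syndrome's critical region, reportable at full
  probe resolution regardless of size, nor
* **adjacent** to a reportable call (within a configurable gap on the same
  chromosome), so that contiguous rearrangement products are co-reported.

Because masking is software, the stored trace can later be "unmasked" — a
postnatal full-resolution reanalysis without a new test — and the target
set can be edited per case (e.g. adding an *RBM8A* region for a referral
suggestive of TAR syndrome) or as knowledge evolves.

Recurrent susceptibility loci with incomplete penetrance (15q11.2
BP1–BP2, distal 1q21.1, proximal 16p11.2) are deliberately *not* targets;
the shipped configuration records them as named exclusion regions, both as
documentation and as a veto: a default target can never report a call
whose only overlap lies inside an exclusion. Case-specific targets
override exclusions, which is exactly the TAR scenario — the *RBM8A*
locus sits inside the excluded 1q21.1 region yet must be reportable for
that one referral.

## The segmentation statistic

The commercial aberration-detection algorithm used on the original
platform (ADM-2) is proprietary; this package implements a documented
stand-in that honours its published interface — a score threshold
(default 6) and a minimum-probe rule (3). For probes $i..j$ with log2
ratios $x_k$ and error estimates $\sigma_k$:

$$ S(i,j) \;=\; \frac{\left|\sum_{k=i}^{j} x_k/\sigma_k\right|}{\sqrt{j-i+1}} $$

i.e. the absolute quality-weighted mean z-score scaled by $\sqrt{n}$.
Calling is greedy maximal-score extraction: the highest-scoring interval
with $S \ge$ threshold and enough probes is emitted, its probes are
masked, and the search repeats on the flanks. An exhaustive $O(n^2)$
search (`exhaustiveBestInterval`) is kept in the package as an
independent oracle; a property-based test checks on hundreds of random
series that the top greedy call equals the exhaustive optimum whenever
any interval passes the threshold. Ties break to the longer, then
leftmost interval. Segment boundaries are the outermost probe
coordinates — no midpoint extension — matching how probe-delimited
coordinates appear in diagnostic result strings.

$\sigma$ defaults to a single per-array robust estimate, the
derivative-spread estimator $\mathrm{MAD}(\Delta x)/\sqrt{2}$, which is
insensitive to the CNVs themselves; per-probe errors are accepted when
the input provides them. Non-finite ratios are dropped with a logged
count.

Copy states map the segment mean back to integer copies
($c = r \cdot 2^{\bar x}$, rounded; reference $r$ is 2 for autosomes,
sex-aware on X/Y): estimates of 5 or more copies are reported as
amplifications (`amp`), and a mean |log2| inside the mosaic window
(default 0.25–0.8) yields a bracketing mosaic pair such as `x1~2`.

## Channel disambiguation

Two diagnostic samples are co-hybridized per array, so a ratio shift
alone cannot say which sample carries the CNV. For each called region the
package compares each dye channel's raw intensities against the
*run-median* of the same channel across run-mate arrays whose own call
sets are clean over that region (default: at least 5 eligible
references, matching the production batching of 6 arrays per run). The
deviation is the median over call-region probes of log2(intensity /
reference median). The carrier is the channel whose absolute deviation
reaches the threshold (default 0.3, about half a heterozygous-deletion
shift) with the sign implied by the call — for the cy3 channel the sign
of the ratio shift, for cy5 the opposite — while the other channel stays
below threshold. Anything else is retained as "ambiguous", and runs
that cannot field enough references fail loudly rather than guess.
Once a carrier is known, the copy state is re-estimated from the
carrier-adjusted mean (the ratio inverts when cy5 carries the change).

## The synthetic-data generator

`makeDesign`/`simulateRun` emulate the production design: ~60 bp probes
placed uniformly over hg19 (60,000 by default, optionally densified in
targeted regions), two samples per array, several arrays per run. Per
probe, array and channel the intensity is

$$ I = 2^{B + a_i}\cdot\frac{c_i}{r_i}\cdot 2^{\varepsilon},\qquad
   a_i \sim N(0, 0.2^2),\; \varepsilon \sim N(0, 0.2^2) $$

with $B$ a constant baseline, $a_i$ a per-probe affinity shared by all
arrays of a run — the structure that makes cross-array reference
normalization informative — and $\varepsilon$ independent log2 noise.
Mosaic fractions blend copies linearly; zero-copy probes (chrY in XX)
fall to a small background. The per-probe log2-ratio noise is therefore
$0.2\sqrt{2}\approx 0.28$, typical of a well-behaved clinical array-CGH
hybridization. Truth CNVs are snapped to probe spans, so boundary
accuracy is probe-limited by construction and truth matching uses
reciprocal overlap (default 0.5 for matching, 0.9 when scoring recovery).

Default truth CNVs are heterozygous deletions and duplications, equally
likely, sized uniformly 1–5 Mb: the syndromic-critical-region to
backbone scale this assay exists to detect. The lower edge is a power
decision made from the statistic itself, before any validation run: a
heterozygous duplication shifts the ratio by $\log_2(3/2)=0.585$, i.e.
$z\approx2.07$ per probe at the default noise, so a $k$-probe duplication
scores $\approx2.07\sqrt{k}$ and only clears threshold 6 with margin from
$k\approx14$ probes (~0.7 Mb at backbone density); deletions
($z\approx3.5$) are comfortable from 5–6 probes. Sub-megabase
duplications at backbone probe density are genuinely marginal for any
threshold-6 interval statistic — that is a property of the assay design,
and the simulator's defaults describe the regime the strategy claims,
not the regime it cannot see.

What the simulator does **not** model: dye bias and dye swaps, GC waves,
background subtraction, centralization artifacts, or the upstream
feature-extraction step — simulated intensities are already comparable
across channels, which the real pipeline achieves upstream. Passing
tests therefore demonstrate the logic of calling, disambiguation and
masking under idealized array noise, not robustness to every laboratory
artifact.

## Fixtures and the cohort theorem

The published cohort's CNV tables ship as checksummed TSV fixtures: 23
reported prenatal results (25 CNVs — two samples carry two CNVs each),
23 retrospective deletions and 23 retrospective gains (46 CNVs in 44
fetuses; two footnoted pairs each share a fetus). The package's central
reproduction is a theorem over these fixtures: under the shipped default
configuration plus the documented RBM8A case addition and the adjacency
rule, **every** reported sample classifies abnormal and **all 46**
retrospective CNVs classify masked. This pins the default target
coordinates: the published target list gives chromosome bands only, so
the shipped intervals are a reconstruction from established syndrome
critical regions (DECIPHER-style, hg19), constrained by the fixtures —
whole bands would be wrong, since several masked CNVs fall inside
targeted bands (15q11.2 BP1–BP2, 22q11.23).

Derived statistics recomputed from the fixtures: 23/342 = 6.7% abnormal;
46 additional CNVs in 44/249 = 17.7% of reanalyzed cases; exactly two
masked CNVs between 2 and 3 Mb; deletion sizes 3,252 bp to 2,091,607 bp
(printed as "3 kb to 2 Mb"; note 2,091,607 bp rounds to 2.1 Mb at 0.1 Mb
precision and to 2 Mb at whole-Mb precision — the summary reports raw
values plus both roundings); gains 516 bp to 2,496,403 bp ("0.5 kb to
2.5 Mb"). The cohort denominators 342 and 249 are stated constants, not
derivable from the tables.

Two transcription quirks are preserved, not resolved: the chr10
duplication start is stored as the gain table prints it (64,902,960)
although the running text says 64,902,961; and the source text counts
"29 regions" against a 24-row target table (some rows bundle a deletion
with its reciprocal duplication syndrome) — the shipped configuration
has one region per printed row.

## The synthetic band map

Result strings name cytogenetic bands, but the published band labels do
not always agree with current UCSC hg19 band boundaries (one 22q11.21
coordinate lies just beyond UCSC's band edge). The packaged band file is
therefore **synthetic**: for each chromosome the band boundaries are
derived from the coordinate-to-band relations implied by the 69 fixture
strings (midpoints between adjacent constrained bands, arms padded to
hg19 chromosome lengths, unconstrained arms collapsed to a single band),
which makes parse-format round trips exact on the cohort. Any real UCSC
`cytoBand.txt` can be substituted via `readCytoband()`.

## Numerical and design choices

* Sizes are 1-based inclusive (`end − start + 1`); ">3 Mb" is strict.
* Target overlap is any overlap of at least 1 bp (configurable): a
  deletion clipping a critical region is clinically reportable.
* The adjacency rule (same chromosome, gap ≤ 1 Mb between closed
  intervals, iterated to a fixed point) is a reconstruction: the cohort
  reports a 1.98 Mb sub-threshold deletion together with its contiguous
  38 Mb duplication, but no explicit rule was published. The gap counts
  bases strictly between the intervals and is fully configurable, and
  every promotion is recorded in the call's reasons.
* Per-target direction filters (`loss`/`gain`/`both`) exist because
  distinguishing reduced from increased copy number is the stated next
  refinement of the strategy; every default target ships as `both`,
  since the published cohort did report 22q11.2 duplications.
* Exclusion regions never suppress backbone calls; they only veto
  default-target matches, and only when the entire call-target overlap
  lies inside the exclusion.
* Determinism: every stochastic step takes an explicit seed; pipeline
  outputs carry no timestamps and manifest paths are relative, so
  identical seeds give byte-identical output trees. Classified call sets
  and reports embed a hash of the configuration used.
* Ambiguous carrier assignments keep the call (attributed to both
  samples of the array, flagged), so masking decisions never silently
  drop an aberration.

## Problem sizes used by the test suite

Unit tests run on compact designs (hundreds to a few thousand probes on
one- or two-chromosome toy genomes) chosen so each property is exercised
in milliseconds. The cohort-level recovery check simulates 200
six-array runs on a full 60,000-probe hg19 design with three injected
CNVs each (600 truth CNVs), measuring recovery at reciprocal overlap
0.9, carrier accuracy and ambiguity rate; the oracle-equivalence
property uses 500 random series of up to 200 probes. These sizes are the
package's own validation design.

## Known limitations

* Reference eligibility for channel assignment is call-based only; sex
  mismatches between run-mates can bias X/Y deviations (production
  pairing is sex-matched, and the simulator's default is too).
* Copy-state estimation during segmentation assumes autosomal reference
  copies until a carrier is assigned; X-linked states are re-oriented
  only after disambiguation.
* The greedy caller is transparent but not globally optimal for
  multi-aberration chromosomes; the oracle test pins its behaviour on
  the dominant call, which is the clinically decisive one.
* Only the CNV result-string dialect is parsed — not full ISCN
  karyotype nomenclature (no translocations or inversions, which array
  CGH cannot see anyway).
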