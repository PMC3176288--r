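---
title: "Methods: bisulfite clone methylation, dual-mapper consensus and Methyl-DIP enrichment"
author: "mirmeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bisulfite clone methylation, dual-mapper consensus and Methyl-DIP enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeth)
```

# Scope

mirmeth implements the computational analysis of a study design in which a
miRNA gene's upstream CpG island is interrogated three ways — base-resolution
bisulfite clone sequencing, affinity capture of methylated DNA (Methyl-DIP)
with interval-level read quantification, and a dual-mapper RNA-seq screen for
genes responding to restored miRNA expression — alongside quantitation of the
cell-biology readouts (adhesion, Matrigel invasion, scratch-wound motility,
comparative-Ct qPCR). Because such studies rarely deposit raw reads or clone
chromatograms, every analysis stage is paired with a seeded synthetic-data
generator that emulates its inputs with known ground truth; the test suite
and the acceptance script exercise the full simulate–analyse loop.

# Bisulfite clone sequencing

## Model

Sodium bisulfite deaminates unmethylated cytosine to uracil (read as T after
PCR) while 5-methylcytosine is protected. `bisulfiteConvert()` applies
exactly this chemistry to the plus strand: every non-CpG C, and every
unmethylated CpG C, is converted with probability equal to the conversion
efficiency; methylated CpG Cs are never converted. Efficiency 1 makes the
operation deterministic, and calling is then an exact left inverse of
conversion: `callMethylation()` reads C at a CpG as methylated, T as
unmethylated, and anything else as ambiguous, by straight positional
comparison against the native amplicon. Indel-tolerant alignment is
deliberately out of scope — clones are assumed full-length, which keeps calls
deterministic and testable, and which the synthetic generator guarantees.

Sites are called on the plus strand only, matching the single-strand design
of bisulfite PCR: each amplicon sequences one converted strand.

## In-silico PCR

`insilicoPcr()` matches primers exactly (zero mismatches) against the fully
converted plus strand, with CpG cytosines represented as the degenerate base
Y (C or T). A primer that overlaps a CpG therefore matches both methylated
and unmethylated templates — the behaviour a well-designed bisulfite pair
must have. Zero placements and multiple placements are both hard errors;
the package never silently picks a best hit, because a mis-placed amplicon
would silently shift every downstream CpG column.

## Quality control and classification

Each clone's conversion rate — the fraction of non-CpG reference cytosines
read as T — is the standard check for incomplete conversion.
`siteFrequencies()` excludes clones below 0.95 by default (overridable).
Note a consequence quantified in the tests: at efficiency $e < 1$, an
unmethylated CpG escapes conversion with probability $1-e$ and is then
*correctly read* as methylated at the molecule level, so the expected
per-site call frequency is $q = p + (1-p)(1-e)$ for generating methylation
probability $p$. The closed-loop tests therefore check observed frequencies
against the binomial law of $q$, which is the true sampling distribution of
the estimator; only at $e = 1$ does $q = p$ and recovery become exact.

`classifyHypermethylation()` labels a sample hypermethylated when the mean
per-site frequency over non-excluded sites reaches a threshold, default 0.3.
The threshold is a configuration knob, not a constant: in this assay design
benign samples sit near 0 and hypermethylated tumours near 0.9, so any
threshold in a wide band separates them; 0.3 leaves a symmetric margin. The
default exclusion of sites 2 and 3 reflects the two 5'-end CpGs that are
methylated even in keratinocytes and normal skin in this amplicon design and
so carry no tumour signal. Because absolute coordinates for those sites are
assay-specific, the exclusion list is an argument (site indices), not a
hard-coded fact.

```{r bisulfite-demo}
ref <- genReference(seed = 3)
cohort <- genCloneCohort(ref,
  data.frame(sample_id = c("mel", "tumour"),
             class = c("melanocyte", "stage3"),
             meth_prob = c(0.02, 0.9)),
  cloneCount = 9, seed = 5)
mats <- callCloneCohort(cohort$clones, ref)
classifyHypermethylation(mats$tumour)[c("classification", "meanFrequency")]
renderCloneMatrix(mats$tumour)
```

# Dual-mapper expression consensus

## The procedure

Each mapping pipeline contributes per-gene RPKM
($\mathrm{RPKM} = c \cdot 10^9 / (L \cdot N)$ for count $c$, length $L$ bp,
library size $N$). Fold changes use a pseudo-count of 1.0 in numerator and
denominator, reported in the symmetric signed convention ($+r$ for
$r \ge 1$, $-1/r$ otherwise), so thresholds like $\pm 1.5$ apply directly
and `foldChange(a, b) == -foldChange(b, a)`. A gene is accepted only when
both mappers agree on direction; the corroborated fold change is the
*smaller* magnitude of the two (conservative, mapper-symmetric, monotone),
and genes are ranked by its magnitude with lexicographic tie-breaks so
re-runs are byte-identical.

Three design points were genuinely open and are resolved as follows:

* **Transcript delta.** Implemented as the mean over mappers of the
  case-minus-control RPKM difference: it is thresholded on the same scale
  as other RPKM-derived quantities, and the choice is isolated in
  `consensusMerge()` should a count-difference variant be wanted.
* **Corroboration rule.** Minimum magnitude rather than mean or a
  designated mapper: any gene it promotes is supported by both pipelines.
* **Cutoff sets.** The three screens are kept as data
  (`defaultCutoffs()`): open reading frames $|FC| \ge 1.5$ and
  $|\Delta| \ge 10$; miRNA up-screen $FC \ge 1.5$, $\Delta \ge 1.3$;
  target-candidate down-screen $FC \le -1.2$, $\Delta \le -2.0$. The
  miRNA screen is one-sided up and the target screen one-sided down,
  matching their roles (an up-regulated miRNA list; candidate targets of a
  restored repressor must fall).

Genes with zero RPKM everywhere are dropped before ranking (their fold
change is identically +1). No multiple-testing control is applied: the
procedure is a fold-change/delta screen by construction, and the planted
recovery tests characterise its operating point instead.

`filterTargets()` intersects the down-screen survivors with the top-N
(default 500) ranks of an externally supplied predicted-target list,
preserving consensus order — prediction itself is out of scope.

## What the simulator emulates

`genCountTables()` draws one biological truth observed by two mappers:
negative-binomial counts (dispersion 0.1 by default; 0 gives Poisson)
around expected values proportional to expression × length × library size,
where each mapper applies its own per-gene lognormal factor (σ = 0.1)
*shared between conditions* — it models mapper bias, so it cancels in
within-mapper fold changes but perturbs deltas — and its own library size
(raw reads × 0.63 mapping rate × per-mapper unique fraction 0.89/0.83,
typical short-read mapper statistics). Baseline expression is zero-inflated
lognormal: 60% of genes essentially silent, expressed genes with median
1 RPKM (σ~log~ = 1.0). This moderate-expression catalogue keeps the screen's
behaviour near its thresholds visible; real transcriptomes carry a heavier
high-expression tail (housekeeping genes at hundreds of RPKM), for which a
plain fold-change screen without replicates admits more concordant noise
than the defaults exhibit — a limitation of threshold screens generally,
not of the simulation. Planted differentially expressed genes (50 of 2000
by default) get baseline RPKM uniform in [20, 100] and signed fold-change
magnitudes uniform in [3, 8], so their planted deltas clear the delta
cutoff several-fold, the regime in which recovery is informative.

Under these defaults the full pipeline recovers ≥ 97% of planted genes at a
false discovery proportion below 1%, and a null scenario yields a median of
0 survivors over 20 seeds (occasional seeds yield 1–3 concordant
fluctuations; with dispersion 0.1 and no replicates that cannot be reduced
to exactly zero in every seed).

# Methyl-DIP interval enrichment

Capture enrichment is quantified as interval RPKM with fragment-count
semantics: fragment counts per island are supplied directly (the on-disk
format is a bedGraph-like TSV with a `#library_size` header), and
`intervalRpkm()` applies the same reads-per-kilobase-per-million formula.
Enrichment between conditions is the pseudo-count ratio of interval RPKM.

The simulator models the enrichment step mechanistically: fragments with
truncated-normal lengths (mean 250 bp on [50, 400] — the shearing target of
the protocol being emulated) are placed uniformly; a fragment's methylated
CpG content is Poisson around overlap × island CpG density × methylation
level; capture is Bernoulli with logistic probability in that count
(intercept −4, slope 0.6: ~2% background capture, ~88% at 10 methylated
CpGs). Any overlap assigns a fragment to an island — islands are far apart,
so the simplest deterministic rule suffices. With `noise = FALSE` the
generator integrates the placement and length distributions on a grid and
returns expected counts, the regime in which enrichment ratios are exactly
monotone in the generating methylation level (rank correlation 1 across a
10-island gradient). Histogram bin width for display purposes is not fixed
by the method; islands are the natural quantification unit here.

# Phenotype assays

* `percentBound()`: percent of seeded cells attached, mean ± SEM
  (SEM uses the n−1 sample standard deviation — the usual convention).
* `percentInvasion()`: 100 × mean invading cells / mean wild-type cells
  migrating through the control membrane; the control against itself is
  exactly 100%.
* `woundClosure()`: both labellings are reported explicitly — closure
  percent $100(1 - A_t/A_0)$ and area-remaining percent $100 A_t/A_0$ —
  because they differ only by $100 - x$ and mislabeling one as the other
  flips the conclusion. Wound expansion appears as negative closure rather
  than an error.
* `relativeQuantity()`: comparative-Ct, $RQ = 2^{-\Delta\Delta C_t}$.

## Kruskal–Wallis

The test is implemented from ranks directly: midranks for ties, the
standard tie-correction divisor, and H referred to $\chi^2_{k-1}$ only when
every group has at least five observations. Below that — the typical
triplicate assay, where the chi-square approximation is unreliable — the
exact permutation distribution over all distinct assignments of the pooled
observations to the group sizes is enumerated (capped at 5 × 10^5
assignments, beyond which the approximation is used with a warning). With
two groups of three, the smallest attainable p-value is 0.1: worth knowing
when a triplicate design is expected to show "significance". Degenerate
input (all observations identical) returns H = 0, p = 1. The tests verify
H against the independent reference implementation in `stats` and exact
p-values against full enumeration, and the chi-square branch holds its
nominal 5% size within Monte-Carlo error over 10^4 null simulations.

The assay simulator (`genAssayData()`) uses saturating adhesion kinetics,
linear-to-complete wound closure and Poisson invasion counts, with effect
multipliers (defaults 0.6 adhesion, 0.5 invasion, 0.5 wound rate, i.e. the
reduced-adhesion/invasion/motility direction) and 10% lognormal replicate
noise. It emulates summary-level behaviour only — no image segmentation, no
spatial structure, no plate effects.

# Numerical and interface conventions

* Coordinates are 1-based inclusive internally (the `GRanges` convention);
  BED and bedGraph-like files are 0-based half-open on disk and converted
  once at the I/O boundary.
* All tables are tab-separated with `#key=value` metadata headers; the run
  seed is recorded in every generated output.
* Every generator is a pure function of (parameters, seed) with a private
  RNG stream, so generation never perturbs the caller's RNG; clone-level
  noise uses one stream per clone (seed + clone index) for clone-wise
  reproducibility. All truth is emitted in machine-readable tables, and
  recovery tests read truth only from those.

# Problem sizes

The shipped tests and the acceptance script use desk-scale problem sizes
chosen to make the statistical checks sharp while staying quick: ~500
clones across nine (efficiency, methylation) conditions; 1,000 six-clone
samples for classification recovery; 20 seeds × 2,000 genes × 50 planted
for the consensus screen; 10 islands × 2 × 10^5 fragments per condition
for capture; 10^4 permutation/null draws for the statistical calibrations.

# Known limitations

* Clone calling is positional; real Sanger clones with indels need prior
  alignment, which is out of scope.
* The expression simulator's moderate-tail baseline understates the
  high-expression false-positive pressure a plain threshold screen faces
  on real transcriptomes (see above).
* The capture model ignores CpG-density bias and fragment GC effects; it
  is designed to validate monotonicity and ratio arithmetic, not to fit
  real MeDIP coverage.
* Patient-style cohorts mixing hyper- and hypomethylated samples are
  illustrative scenarios, not estimates of population prevalence.
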