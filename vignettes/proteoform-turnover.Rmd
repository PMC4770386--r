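---
title: "Measuring N-terminal proteoform turnover: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring N-terminal proteoform turnover: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proturn)
```

## The measurement

In a pulsed SILAC (pSILAC) experiment with a label swap, cells
pre-labelled with a medium arginine isotope are switched into heavy
medium at time zero. From that moment, protein made before the switch
carries the medium label and decays, protein made after the switch
carries the heavy label and accumulates, and a light-labelled reference
proteome mixed in at harvest provides the denominator. For every
N-terminal peptide quantified at timepoint $t$, the two ratios $M/L$
and $H/L$ therefore report degradation and synthesis of the proteoform
that peptide represents. Because positional (N-terminomics) enrichment
resolves protein start sites, the same gene can contribute several
proteoforms — the database-annotated N-terminus (dbTIS), downstream
alternative initiation products (aTIS), and partially processed
initiator-Met variants — each with its own time course.

## The turnover model

When pre-existing plus new protein accounts for the reference amount
($M + H = L$), the normalized fractions satisfy $m + h = 1$ with
$m = \frac{M/L}{M/L + H/L}$. `normalize_ratios()` enforces this
identity unconditionally and `time_course()` flags observations where
$|(M+H)/L - 1| > 0.5$, since a large imbalance indicates a
quantification problem that renormalization silently hides.

Degradation is modelled as a first-order process observed in a
proliferating culture, so the apparent decay combines true degradation
with dilution by cell division:

$$ m(t) = e^{Bt}, \qquad B = -k_{deg} - \frac{\ln 2}{t_{cc}} $$

`fit_exponential()` estimates the single parameter $B$ by nonlinear
least squares *in ratio space*. Fitting $\log m$ by linear regression
would be algebraically convenient but reweights the measurement noise
(late, small $m$ values would dominate); the ratio-space fit treats all
timepoints on the measured scale. The optimizer is Levenberg–Marquardt
started from the through-origin log-linear slope of the positive $m$
values, with a bounded golden-section search over the residual sum of
squares as a fallback if the iteration fails. $R^2$ is the conventional
$1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ taken about the mean of the
observed $m$.

Three quantities follow from $B$ at the configured doubling time
$t_{cc}$ (default 24 h, measured from a growth curve via
`doubling_time()` as $\ln 2 / r$):

* the 50% turnover time $t_{turn} = \ln(1/2)/B$, the time at which the
  degradation and synthesis curves cross (both equal $1/2$);
* the degradation rate constant $k_{deg} = -B - \ln 2 / t_{cc}$;
* the half-life $t_{1/2} = \ln 2 / k_{deg}$, reported as `Inf` when
  $k_{deg} \le 0$ — a proteoform whose apparent decay is explained
  entirely by dilution is, on this assay's timescale, not degraded.

A useful internal consistency check falls out of the algebra: a
non-degraded proteoform ($k_{deg} = 0$) has $t_{turn} = t_{cc}$
exactly, so the doubling time marks the stability boundary on the
turnover scale.

## Filters and the linear fallback

`compute_turnover()` applies the decision cascade in a fixed order:

1. proteoforms observed in fewer than 3 timepoints (configurable) are
   excluded outright;
2. an exponential fit with $R^2 \ge 0.8$ and $B < 0$ supplies
   $t_{turn}$ directly;
3. otherwise, if the profile descends (negative Spearman correlation of
   $m$ against $t$) and two consecutive observations bracket $0.5$, the
   turnover time is interpolated linearly between them
   (`linear_crossing()`; because $h = 1 - m$, the chord intersection
   equals the $t$ at which interpolated $m = 0.5$);
4. otherwise the proteoform remains unassigned (`method = "invalid"`),
   a value rather than an error.

$k_{deg}$ and $t_{1/2}$ are always derived from the exponential $B$
when a fit exists, whichever method supplied $t_{turn}$. When noise
produces several bracketing pairs, the earliest is used — a
deterministic tie-break. Observed $m > 1$ is kept as-is for fitting;
clipping would bias the early timepoints where $m \approx 1$.

The "descending trend" requirement for the fallback is not quantified
in prose anywhere; we operationalise it as a strictly negative Spearman
correlation, which is scale-free and robust to a single noisy point.

`subsample_turnover()` refits every $k$-subset of the observed
timepoints (default $k = 3$) and returns the multiset of turnover
times from subsets passing the $R^2$ gate — the standard way to ask
how many observations the model actually needs.

## Proteoform classification

Initiator-Met removal by methionine aminopeptidases is expected when
the second residue has a small gyration radius: Ala, Val, Ser, Thr,
Cys, Gly, Pro (`IMET_CLEAVABLE`). Some descriptions of the rule omit
Ser; the residue set is therefore an argument everywhere it is used.
`classify_peptide_start()` maps each peptide to one of three
categories: starts at positions 1/2 are dbTIS (position 2 only when
residue 2 permits removal — a position-2 start behind, say, Met-Leu
violates the rule and is flagged non-compliant rather than silently
kept); downstream starts are aTIS when they begin with Met or follow a
Met with a cleavable first residue; everything else is a candidate
proteolytic product and excluded from turnover comparisons. The rules
are deterministic, so on synthetic proteomes classification recovers
the generator's truth exactly — that property is asserted in the test
suite.

When both the Met-retaining and Met-processed form of one start codon
are observed, `select_mature_nterminus()` keeps only the form expected
from the rules, so downstream statistics see one N-terminus per
proteoform. `assign_origin()` resolves the most likely origin of each
aTIS from pre-joined evidence flags with the precedence
splicing-likely (database isoform match at position 1/2 with transcript
support level ≤ 3) → alternative initiation (direct Ribo-Seq or
Nt-acetylation evidence) → splicing-poor → proteolysis candidate
(protease-knowledgebase match with neither acetylation nor Ribo-Seq
support). Confidence is monotone in evidence: adding a flag can never
demote a confident record.

## TIS calling from ribosome profiling

Lactimidomycin (LTM) traps initiating ribosomes, cycloheximide (CHX)
elongating ones, so an initiation site appears as an LTM peak over CHX
background. P-site positions are obtained from read 5′ ends with
length-dependent offsets (+12 for ≤ 30 nt, +13 for 31–33 nt, +14 for
34 nt; reads outside 26–34 nt are discarded). The calling score is the
difference of library-normalized signals,
$R_{LTM-CHX} = s\,(\mathrm{ltm}/N_{ltm} - \mathrm{chx}/N_{chx})$.
The normalization constant $s$ is not fixed by any convention we could
adopt; it defaults to $10^7$ (per ten million mapped P-sites) and is
configurable, which means absolute $R$ values are only comparable
between runs using the same scale.

Per-category thresholds (`tis_thresholds()`): annotated starts need
LTM count ≥ 5, $R \ge 0.01$ and must be the local maximum of the LTM
signal within a 7-nt window (one codon each side); CDS-internal
positions need count ≥ 15 and $R \ge 0.15$; UTRs and non-coding
transcripts need count ≥ 10 and $R \ge 0.05$. The local-maximum rule is
stated only for annotated starts but applied to all categories by
default (configurable), because downstream positions are flanked by
elongation signal on both sides and benefit from the same peak logic.
Window ties break toward the 5′-most position — a deterministic choice
where none is prescribed. Coordinates are transcript-local, 0-based,
half-open throughout; the bedGraph reader/writer handles the external
convention.

`match_peptides_to_tis()` closes the loop: a proteoform is Ribo-Seq
supported when a passing call sits at the codon of its initiator Met —
for processed N-termini (including position-2 database starts), the
codon of the Met immediately preceding the observed start residue.

## Abundance and sequence features

Spectral counts are averaged over the timepoints in which a proteoform
was identified (absent timepoints are excluded, not zero-filled);
NSAF$_i = (SpC_i/L_i)/\sum_j SpC_j/L_j$ uses the *mature* proteoform
length (database length − start + 1), because proteoforms are
start-specific, and the normalization runs once over the full dataset
of mean counts rather than per timepoint. GRAVY is the mean
Kyte–Doolittle hydropathy of the first 2 or 10 residues. Disorder
percentages and ubiquitination evidence are pass-through input columns:
they come from external predictors and experimental compilations that
this package deliberately does not reimplement.

## The comparison suite

All group comparisons are nonparametric: one-sided Mann–Whitney for
independent groups (aTIS vs dbTIS turnover, abundance; ubiquitinated vs
lysine-matched non-ubiquitinated), one-sided Wilcoxon signed-rank for
dbTIS/aTIS pairs from the same gene, Kruskal–Wallis across N-terminal
residue groups with two post-hoc procedures — the critical-difference
test on mean ranks ($|\bar R_i - \bar R_j| >
z_{1-\alpha/k(k-1)}\sqrt{\tfrac{N(N+1)}{12}(\tfrac1{n_i}+\tfrac1{n_j})}$)
and uncorrected pairwise Wilcoxon tests. Exact p-values are used for
small samples without ties and the normal approximation otherwise; for
small groups `residue_group_analysis(exact = TRUE)` computes the
Kruskal–Wallis p by complete enumeration of group assignments instead
of the chi-square approximation. `enrichment_1d()` is a deliberately
simple 1D enrichment: per category, a two-sided Mann–Whitney of
in-category against out-of-category values with Benjamini–Hochberg
correction across categories and a direction label; categories with
fewer than two members or non-members are skipped.
`extreme_decile_analysis()` applies it to the 10% most and least stable
records. Identical paired samples leave no signed ranks and are
returned as a flagged degenerate result rather than an error.

### A caution on the complex-dispersion test

`complex_dispersion()` follows the published construction exactly: for
each member of a complex (≥ 3 quantified members), its absolute
turnover differences to every other member are compared, by one-sided
Mann–Whitney at $\alpha = 0.05$, against the pairwise differences among
the remaining members. The reference set excludes pairs involving the
tested member, which keeps the candidate's own differences out of the
reference. Users should know that this test is **anticonservative by
construction**: all values in the test set share the tested member's
own turnover, so the two samples are dependent and the Mann–Whitney
null distribution does not hold. In simulations with exchangeable
members the per-member flag rate at $\alpha = 0.05$ is ≈ 13% for
8-member complexes, and the probability that *some* member of a null
complex is flagged grows quickly with complex size. The flags are
excellent at ranking genuine outliers (a 20 h shift in an otherwise
tight complex is detected essentially always, and the planted member is
the one flagged), but the nominal α should not be read as a calibrated
false-positive rate, and complex-level "has-outliers" labels on real
data will include a substantial background. Three-member complexes can
never be flagged at all: the smallest attainable exact p with 2-vs-1
differences is 1/3.

## What the synthetic data emulate — and what they do not

The generators reproduce the study conditions so that every stage can
be tested against known truth:

* `generate_proteome()` — random proteomes (50–1000 residues) in which
  20% of genes by default carry a downstream aTIS whose Met offset is
  lognormal with median 52 residues (matching the observed offset
  distribution centred within the first 200 residues); second residues
  split evenly between cleavable and non-cleavable so both iMet fates
  occur; 5% of cleavable genes also yield a retained/processed pair.
  True 50% turnover times are lognormal with median 21.6 h (the
  observed cohort median) and sdlog 1.1, spanning under 1 h to beyond
  48 h at cohort size. The true decay parameter and degradation
  constant derive from the turnover time; note that drawing a strictly
  positive $k_{deg}$ could never produce turnover beyond $t_{cc}$, so
  the turnover time, not $k_{deg}$, is the primitive — proteoforms more
  stable than the dividing culture then carry a (true) negative
  $k_{deg}$ and exercise the infinite-half-life rule.
* `simulate_psilac()` — the forward model $m(t) = e^{Bt}$ on the
  experimental grid (0.5, 1.5, 4, 8, 12, 24, 48 h) with multiplicative
  lognormal noise per channel (σ = 0.1 default; intensity noise in MS
  is approximately multiplicative), per-timepoint missingness (0.15
  default), Poisson spectral counts with aTIS abundance down-weighted
  by 0.5, and a small fraction (0.01) of monotone logistic decay
  profiles steep enough to fail the $R^2$ gate, exercising the linear
  fallback.
* `simulate_ribotracks()` — Poisson CHX background over the CDS
  (0.1 reads/nt default), LTM at a tenth of that plus planted peaks
  (50 reads) at every true initiation codon.
* `generate_complexes()` — complexes of 3–10 members with tight shared
  turnover (sd 0.5 h) and, in half of the complexes, one member shifted
  by 20 h.

They do **not** emulate raw spectra, peptide-spectrum matching,
chromatographic effects, arginine-to-proline conversion, read alignment
or multi-mapping. Passing tests on synthetic data therefore demonstrate
that the *computational* rules behave as specified under a plausible
noise model — not that the noise model captures a real instrument. The
lognormal σ is a stand-in; no quantitative MS noise model was available
to copy.

## Numerical choices and problem sizes

Fits converge to the true $B$ within $10^{-6}$ on noise-free data (the
suite asserts $<10^{-6}$ over a 1000-proteoform cohort, and the
Levenberg–Marquardt tolerances are set to $10^{-14}$). The agreement
between the exponential and linear turnover estimators is checked on a
500-proteoform cohort at σ = 0.1, where their Pearson correlation is
≈ 0.995 (the reproduction script in `scripts/acceptance.R` recomputes
this from scratch); the two estimators are also required to agree
within 2% on noise-free data, bounding the chord-vs-curve bias on the
7-point grid. Exact-test oracles enumerate up to $\binom{16}{8} =
12{,}870$ Mann–Whitney arrangements and $2^8$ sign patterns; exhaustive
Kruskal–Wallis enumeration is kept to totals where the full permutation
set is computable in seconds. Complex-dispersion calibration runs 1000
simulated complexes. These sizes were chosen to estimate each property
with comfortable margin while keeping the default test run fast.

## Known limitations

* No amino-acid recycling term: the model assumes complete label
  replacement, which held for the motivating dataset but not for all
  cell systems; two-phase decay is out of scope.
* The $R_{LTM-CHX}$ normalization constant is a convention; published
  absolute thresholds are only meaningful relative to the same scale.
* The complex-dispersion test's nominal α is not calibrated (see
  above).
* Disorder prediction, GO/Pfam/KEGG annotation and database search are
  external; the package consumes their outputs as columns.
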