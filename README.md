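# proturn

Turnover analysis for **N-terminal proteoforms** measured by positional
proteomics. Genes frequently produce several protein forms that differ
only in their N-terminus — the database-annotated start (dbTIS),
downstream alternative initiation products (aTIS), and variants of
initiator-methionine processing — and these forms can have different
stabilities. `proturn` implements the complete computational pipeline
for such studies: it classifies N-terminal peptides by the rules of
iMet processing, fits pulsed-SILAC isotope-ratio time courses with a
one-parameter exponential turnover model, derives degradation constants
and half-lives corrected for dilution by cell division, computes
spectral-count abundance (NSAF) and N-terminal hydropathy (GRAVY)
features, calls translation-initiation sites from paired
lactimidomycin/cycloheximide ribosome-profiling tracks, and runs the
nonparametric comparison suite used to contrast proteoform classes.
Synthetic-data generators with known ground truth make every stage
testable without any external download.

It is written for proteomics bioinformaticians analysing
N-terminomics / pSILAC experiments, and for methodologists who want a
tested reference implementation of the turnover model and its filters.

## The model

With a label swap at $t = 0$ and a light reference proteome mixed in at
harvest, the normalized degradation fraction of a proteoform decays as

$$ m(t) = e^{Bt}, \qquad B = -k_{deg} - \frac{\ln 2}{t_{cc}}, $$

where $t_{cc}$ is the cell doubling time (default 24 h). The 50%
turnover time is the crossing of the degradation and synthesis curves,
$t_{turn} = \ln(1/2)/B$; the half-life is
$t_{1/2} = \ln 2 / k_{deg}$, infinite when $k_{deg} \le 0$ (apparent
decay fully explained by cell growth). Fits use nonlinear least squares
in ratio space and must reach $R^2 \ge 0.8$ on at least 3 observed
timepoints; profiles failing the gate fall back to linear interpolation
of the pair of observations bracketing $m = 0.5$, provided the profile
descends; everything else is excluded. See the vignette
(`vignettes/proteoform-turnover.Rmd`) for the full account of the
model, filters, TIS-calling thresholds and design choices.

## Worked example

```r
library(proturn)

# a synthetic cohort with known ground truth
proteome <- generate_proteome(n_genes = 300, atis_fraction = 0.2, seed = 42)
quant    <- simulate_psilac(proteome$truth, seed = 43)

# turnover with the full filter cascade
fits <- fit_turnover(quant, kinetics_config(t_cc = 24))
head(fits, 4)
#>   accession n_timepoints method             B    R2 t_turn_h t_half_h
#> 1 G00001_1             6 exponential -0.00804 0.974    86.2    Inf
#> 2 G00002_2             5 exponential -0.453   0.994     1.53     1.63
#> 3 G00003_2             6 exponential -0.113   0.998     6.15     8.26
#> 4 G00004_1             6 exponential -0.0443  0.997    15.6     45.0
```

Each row is one proteoform: `method` records which branch of the
cascade produced the turnover time, `t_turn_h` is the 50% turnover
time, and `t_half_h` is the dilution-corrected half-life — `Inf` marks
proteoforms whose fitted degradation constant is non-positive. In this
cohort 365 of 368 proteoforms get a valid turnover (the rest were
observed at too few timepoints or never descend through 0.5), the
median turnover is 23.9 h, and 184 proteoforms are effectively
non-degraded over the assay window:

```r
sum(fits$method != "invalid")                       # 365
median(fits$t_turn_h, na.rm = TRUE)                 # 23.9
sum(is.infinite(fits$t_half_h), na.rm = TRUE)       # 184
```

Classify the peptides and compare proteoform classes:

```r
peps <- dplyr::distinct(quant[, c("peptide", "accession", "gene",
                                  "start", "acetylation_evidence")])
ann    <- annotate_peptides(peps, proteome$sequences)
merged <- dplyr::left_join(ann, fits, by = "accession")
a <- merged$t_turn_h[merged$category == "aTIS"]
d <- merged$t_turn_h[merged$category == "dbTIS"]
compare_groups(a[is.finite(a)], d[is.finite(d)],
               alternative = "greater", variable = "turnover")
#>   variable     test         alternative p_value n_a n_b conclusion
#> 1 turnover Mann-Whitney     greater     0.256    61 304 not significant
```

The one-sided Mann–Whitney test asks whether aTIS proteoforms are more
stable than dbTIS proteoforms; in this synthetic cohort turnover is
generated independently of category, so the null result is the correct
answer. `run_pipeline()` chains all stages (annotation, kinetics,
features, optional Ribo-Seq TIS support, statistics) from files on disk
and writes TSV reports plus a manifest with the filter funnel.

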