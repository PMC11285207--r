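---
title: "phipflag: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phipflag: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phipflag)
```

# The scientific problem

Phage-display immunoprecipitation sequencing (PhIP-Seq) reads out antibody
reactivity against a programmed peptide library: peptides pulled down by a
sample's antibodies are enriched in post-IP sequencing relative to their
pre-IP (input) abundance. Applied to bacterial flagellins, this gives a
systemic view of anti-flagellin antibody repertoires in conditions such as
Crohn's disease (CD) and ME/CFS, where responses concentrate on the conserved
N-terminal (D0/D1) and C-terminal (D0) domains that flank the hypervariable
exterior-facing region. Flagellins are further classified by their TLR5
readouts relative to the FliC-PIM mutant reference: *stimulators* (stronger
binding and activation), *silents* (stronger binding, weaker activation,
typical of Lachnospiraceae commensals), and *evaders* (weaker binding and
activation, typical of pathogens such as *H. pylori*).

phipflag implements this pipeline end to end on synthetic or user-supplied
data: enrichment calling under a generalized Poisson null, peptide library
design, domain annotation and epitope-position profiling, class-similarity
statistics, and a seeded synthetic cohort generator with planted
disease-like binding signatures.

# The enrichment model

Post-IP counts for a peptide at input read level $x$ are modelled as
generalized Poisson (Consul's two-parameter form),

$$P(X=k) = \theta(\theta + k\lambda)^{k-1} e^{-\theta - k\lambda}/k!,
\qquad \theta > 0,\; 0 \le \lambda < 1,$$

with mean $\theta/(1-\lambda)$ and variance $\theta/(1-\lambda)^3$;
$\lambda = 0$ recovers the Poisson. The cohort study this package
re-implements names the distribution but not a functional form; this
canonical form is the package's design choice.

Per sample, peptides are grouped into logarithmic input-level bins of at
least `min_bin_obs` (default 200) peptides. Within a bin the rate is tied to
each peptide's exact input level through an offset,
$\theta_i = r_b \, x_i (1-\lambda_b)$, and $(r_b, \lambda_b)$ is fitted by
maximum likelihood. The source protocol estimates parameters *per exact
input read level*; at desk scale (thousands rather than hundreds of
thousands of peptides) per-level counts are too small, and the offset
preserves the per-level mean structure inside a bin exactly. $r$ and
$\lambda$ are then interpolated piecewise linearly on $\log(x+1)$ across bin
centres, giving null parameters at any input level; the interpolated
$\theta$ is projected onto the non-decreasing-in-input cone.

Because truly antibody-bound peptides sit in the fitted data, a naive fit in
a strongly seroreactive sample absorbs them into $\lambda$ (we observed
fitted $\lambda \approx 0.95$ against a generative 0.25, halving
sensitivity). The fit therefore iterates: score all peptides, exclude cells
whose Bonferroni-adjusted upper-tail $p$ falls below 0.05, refit, and repeat
to a fixed point (at most 5 passes). Under the null essentially nothing is
excluded, so calibration is unaffected.

Calling follows the published rules exactly: one-sided upper-tail $p$
(enrichment is directional), Bonferroni adjustment with $m$ = all scored
library peptides, seropositivity at adjusted $p \le 0.05$, fold change
(output/input) only for seropositive peptides with $\ge 25$ input reads and
zero otherwise, per-sample read normalization to 1.25 million identifiable
reads (exclusion below 750,000), and exclusion of samples with fewer than
200 enriched peptides. That last threshold belongs to a 344,000-peptide
library; the desk-scale synthetic pipeline sets `min_enriched = 0`, since
with ~3,000 peptides the published threshold would exclude every sample.

# Library design primitives

Proteins are tiled into peptides of at most 64 aa (54 for the smaller
published design) with 20 aa overlap. The final tile is anchored to end at
the last residue — the protocol states maximum length and overlap but not
terminal handling, and end-anchoring guarantees full C-terminal coverage,
which the C-terminal epitope analysis requires (the overlap of the last pair
may therefore exceed 20 aa).

Reverse translation ranks codons by an E. coli high-expression usage table
(shipped as TSV; any table in the same schema substitutes). EcoRI (GAATTC)
and HindIII (AAGCTT) sites are removed from coding sequences by switching
one overlapping codon to its next-ranked synonym, greedily left to right; an
impossible removal raises an error naming the peptide position. A
`variant_index` selects alternate codons deterministically (mixed-radix over
synonymous positions) so identical peptides remain distinguishable. Short
peptides are padded after the stop codon, with a SwaI failsafe site, to the
fixed oligo length.

Barcodes are random nucleotide codewords accepted greedily under a minimum
pairwise Hamming distance (3 at 44 nt, 5 at 75 nt in the published designs);
the protocol describes the property, not a construction, so an algebraic
code is deliberately not used. Nearest-codeword decoding corrects
$\lfloor(d-1)/2\rfloor$ substitutions and rejects anything farther or
ambiguous.

# Alignment, domains, positions

Pairwise protein alignment is BLOSUM62 with affine gaps (open 11, extend 1)
— the de facto default; the source names tools, not parameters. The
implementation wraps `Biostrings::pairwiseAlignment` (a length-$L$ gap costs
$11 + L$), and the test suite checks it against an independent exhaustive
enumeration oracle on short sequences. Identity is computed over aligned
columns, gaps counting against it.

Domain annotation maps reference N-/C-terminal domain sequences onto a query
by best-scoring local alignment, with structural priors encoding the
empirical boundary distributions: N-domain footprints must start in the
first half of the protein, C-domain footprints must end in the last quarter;
footprints under `min_score` (default 50) are reported absent, which is a
legal result. Relative epitope position is the 1-based start of a peptide
divided by the *full parent protein length* (the figure-caption wording
"peptide length" is read as shorthand for this, following the running text).

Per-peptide prevalence ratios between case and control groups use a
half-subject continuity correction for zero counts (20/100 vs 0/100 gives
$0.2 / 0.005 = 40$), with the published filters (prevalence > 5% in either
group; ratio thresholds 2.5/15/20/25) available but off by default.

# Classification and class-similarity statistics

`classify_reference` is the literal readout rule; the quadrant with weaker
binding but stronger activation than FliC-PIM is undefined in the source and
raises an error rather than guessing, as does equality with the reference.

Class-similarity profiling aligns each antibody-bound flagellin against
every reference of every class at four scopes (full length, peptide,
N-domain, C-domain; domain scopes align domain against domain globally,
peptide scope aligns locally against the full reference). For the paired
battery each query is summarised as its mean identity per class — the
Friedman test needs one scalar per block and class — and contrasts use
Wilcoxon signed-rank post hocs; the unpaired battery is Kruskal–Wallis with
Dunn's z post hocs, both Bonferroni-adjusted over the three contrasts.
Friedman is implemented in-package with midrank tie correction (base R's
returns NaN on fully tied data; here that case is defined as statistic 0,
$p = 1$), as is Dunn (not available in the allowed dependency set); both are
checked against permutation oracles.

# What the synthetic generator emulates — and what it does not

The generator's defaults are the stated world, frozen before any acceptance
run and chosen by power reasoning at desk scale:

* **Panel**: 60 flagellins, 20 per class, mutated from a fixed packaged
  template (synthetic, labelled as such); N domain 135 aa with TLR5 motif
  at 89–110 and hinge at 31–52, C domain 85 aa with allosteric span 30–64,
  hypervariable region 100–180 aa drawn i.i.d. uniform per flagellin.
  Stimulators mutate at 2% background and 1% in the motif; silents conserve
  the motif (3%, strictly weaker conservation than stimulators so the class
  ordering of motif identity is structural) and carry
  a *coherent* silent-lineage sequence at the allosteric span (real silent
  exemplars share ancestry — independent random mutation would make silent
  references mutually dissimilar and erase the C-domain asymmetry the CD
  analysis rests on); evaders descend from fixed evader-lineage domains,
  themselves diverged from the template at ~55% in the TLR5 motif and ~25%
  elsewhere, with 5% within-class noise — pathogen flagellins form their own
  coherent clade, and without a shared lineage an evader query would
  resemble near-template stimulator references *more* than its fellow
  evaders. TLR5 readouts are drawn consistently with class.
* **Library**: panel plus 200 random decoy proteins (100–600 aa), tiled
  64/20; roughly 2,000–3,000 peptides. The real libraries' flagellin
  fraction is unpublished; it is configurable here. Each peptide carries an
  immunogenicity weight (uniform 0.6–1) drawn once per library, so
  per-peptide prevalences vary and correlate across cohorts simulated from
  the same library.
* **Counts**: input is multinomial over lognormal abundances
  (sdlog 1; 200,000 reads/sample); output is generalized Poisson
  ($\lambda = 0.25$, moderate overdispersion) with mean equal to input,
  multiplied for bound cells by an enrichment factor uniform on [20, 100].
  Enrichment acts on the rate with dispersion unchanged — the simplest
  mechanism consistent with fold-change semantics.
* **Cohorts**: 40 cases + 40 controls, age bins and sex drawn from identical
  distributions (balanced by design). The CD-like signature plants
  N-terminal tiles of 8 stimulators + 14 silents (shared with the ME/CFS
  mimic), C-terminal tiles of all 20 stimulators, and a 6-evader tile set at
  low prevalence; the ME/CFS-like signature plants the shared N-terminal set
  plus the evader set at higher prevalence, and no C-terminal binding. Case
  signature prevalence is 0.2 — the top of the source's 10–20% band, needed
  for rank-test power at $n = 40+40$ — against 0.02 in controls. The
  stimulator/silent composition is chosen so the ME/CFS bound set is
  symmetric between stimulator-like and silent-like C-domains (8 stimulators
  + 6 template-like evader C-domains vs 14 silents) while the CD bound set
  is stimulator-heavy (20 vs 14): this encodes, as recoverable ground truth,
  the qualitative finding that C-terminal antibody-bound flagellin sequences
  resemble stimulators specifically in CD.

The generator does **not** emulate: nucleotide-level reads or sequencing
error, phage biology, antibody concentration or affinity, real flagellin
phylogeny (the hypervariable region is i.i.d. uniform), or the real
libraries' scale. A green end-to-end test therefore establishes that the
pipeline recovers planted signal with calibrated error control under the
model's own assumptions — not that it reproduces any printed cohort
statistic, which derives from access-restricted data.

# Numerical choices and degenerate inputs

* GP fitting is L-BFGS-B on the log-likelihood, moment-initialised, with
  $\lambda$ bounded in $[0, 0.98]$; zero-variance samples are refused
  ("no silent nonsense") rather than clamped quietly.
* Upper-tail p-values are complement sums of the pmf, floored at the
  smallest positive double so $p \in (0, 1]$ always holds.
* Zero-input peptides carry no calibration information and are excluded from
  fitting; at scoring time they are assigned the half-read pseudo-level 0.5.
* Read subsampling is sequential multivariate hypergeometric (without
  replacement), deterministic per seed.
* All randomness flows through explicit seeds (`withr::with_seed`); child
  seeds are derived arithmetically below $2^{31}$.
* Exact Wilcoxon p-values are used when both groups have $\le 10$
  observations without ties; the normal approximation with tie correction
  otherwise. Chi-square tests omit the continuity correction (common default
  beyond 2x2 and keeps the hand-computable example exact).

# Known limitations

* The "three distribution parameters ... following interpolation" phrasing
  of the source protocol is ambiguous; the two-parameter-per-bin plus
  interpolation reading is implemented. The alternative (a third pmf
  parameter) is noted, not guessed.
* Whether Bonferroni $m$ is per-sample or library-wide is unstated; the
  library-wide (more conservative) choice is implemented.
* Dunn post hoc power at 40+40 samples is moderate; the CD C-domain
  contrast passes with a real but not enormous margin, which mirrors the
  modest effect in the source rather than an artefact of tuning.
* Alignment tie-breaking follows the backend's deterministic traceback
  rather than a hand-specified diagonal-first rule; outputs are
  reproducible either way.
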