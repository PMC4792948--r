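---
title: "Mapping a recombination crossover point from a randomized site library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recombination crossover point from a randomized site library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmapr)
```

## The problem

Tyrosine recombinases cut and rejoin DNA at a precise inter-base position —
the crossover point. For integron integrases reacting between two identical
double-stranded *attI* sites, the two hybrid junction sites of the
cointegrate are built from moieties of identical parents, so the crossover
point is invisible in the product sequence. When the reaction is too weak
for classical in vitro mapping, a sequencing-based strategy works instead:
build a library of sites in which every molecule carries a single random
base at one of P designated positions spanning the suspected crossover
region, recombine the library, and deep-sequence the two junction sites.
Randomized positions on one side of the crossover stay with one junction
site and positions on the other side go to the other, so the per-position
retention of non-wild-type bases splits at the crossover boundary.

crossmapr implements that whole computational chain: the library design
model, a forward simulator of the recombination reactions and their
sequencing readout, the read-filtering and profiling pipeline, a formal
boundary estimator, and the count-based statistics of the accompanying
plate assays.

## Coordinates and the site model

All sequences are stored as the top strand, 5'→3'; bottom-strand features
are mapped to top-strand coordinates. Crossover points are *boundaries*,
"between base $k$ and $k+1$", never positions: the biology localizes the
exchange between two bases, so boundaries are the inference target. The
randomized window is an ordered list of template positions — not
necessarily contiguous — and window boundaries $b \in \{0, \dots, P\}$ are
expressed between window ordinals, with $b = 0$ and $b = P$ meaning the
exchange falls entirely outside the window.

The bundled `attI1_site()` carries the L box `5'-CCCTAAA-3'` (window
ordinals 1–7), the two spacer bases adjacent to it (ordinals 8–9, `A`,`C`),
and the crossover `C` of the R box (ordinal 10), i.e. the P = 10 design.
The flanking sequence is a synthetic placeholder: the exact genomic flanks
are not part of the model, and every coordinate is configurable through
`site_model()` or a DCF site config. One consequence of this layout is
worth spelling out: the top strand reads `...CCCTAAA AC...`, so a second
`5'-AAC-3'` triplet sits at the L-box border (ordinals 7, 8, 9). The
top-strand crossover falls between the two adenines of that triplet, which
is window boundary $b = 7$ — the bundled `ts_crossover` default. (The
bottom-strand exchange, by contrast, cuts between A and C of the R-box
triplet.)

## The library design and its closed-form distribution

Each library molecule carries exactly one fully random base: one of the P
position sets is chosen (uniformly, weight $1/P$, matching the pooled
construction) and the base at that position is drawn uniformly from the
four-letter alphabet — so a quarter of "randomized" molecules are secretly
wild type. The marginal distribution at a randomized position is therefore

$$\Pr(\mathrm{WT}) = 1 - \frac{1}{P}\cdot\frac{3}{4}, \qquad
  \Pr(\text{each non-WT base}) = \frac{1}{P}\cdot\frac{1}{4},$$

which for P = 10 gives 92.5% wild type and 2.5% per other base, i.e. 7.5%
mutated bases per position. `expected_position_distribution()` returns this
in closed form; `draw_library()` converges to it, and its
`exhaustive = TRUE` mode returns the nominal 40-molecule library
(10 positions × 4 bases; 31 distinct sequences, since each position set
contains the wild-type sequence once).

```{r}
spec <- library_spec(attI1_site())
expected_position_distribution(spec, spec$positions[1])
```

## What the simulator states, and what it does not

The simulator is a first-class, tested module, not a test fixture. Its
defaults are the stated experimental world:

* P = 10 randomized positions, uniform set mixing;
* true top-strand boundary $b = 7$ (the site's annotated crossover);
* sequencing depth 10,000 reads per amplicon class and substitution error
  rate 0.001 — *declared* defaults, since the original experiment's
  per-site depth and error profile were not reported;
* 2% abnormal reads in the end-to-end default;
* equal bottom/top strand reactivity (50/50) in the mismatched-circle
  strand model, matching the observed lack of strand bias; the bias of
  asymmetric reactions is reachable through `bs_prob`.

Reciprocal exchange is pure bookkeeping: the left junction takes donor
ordinals $1..b$ and recipient ordinals $b+1..P$, the right junction the
reciprocal. The replicative pathways copy the single transferred strand,
so the window is not split. Replication after resolution is modelled as
marker copying only — no fork mechanics — because only the marker-level
restriction patterns are testable. Outcomes are a pure function of
(pathway, orientation); the abortive linearization of replicative
resolution between inverted sites falls out of that table.

Sequencing error is substitution-only and uniform, with constant Phred
scores: indel errors are irrelevant to position-indexed profiling at
amplicon scale, and quality-score realism buys nothing here. The three
"abnormal read" corruption modes (truncation, anchor mutation, mid-core
chimera with a 3-base deletion) are this package's own synthetic taxonomy
— the original filtering step is named but not specified — and each mode is
constructed to fail the default filters, so injected labels double as
ground truth for filter tests.

The simulator exposes two granularities. `simulate_junction_profiles()`
works at the window-count level and exists so that parameter-recovery and
power studies over thousands of replicates stay cheap;
`simulate_amplicon_pool()` emits full FASTQ-ready reads and exercises
anchoring, classification and filtering. Both are seeded and
bit-reproducible.

## Read filtering and profiling

Amplicon classes are recognized by their primer contexts: a read belongs
to the class whose left and right anchors both occur (either orientation;
reverse-complement reads are canonicalized to the top strand). The
abnormal-event filter is anchor match within `max_anchor_mismatch`
(default 1) **and** exact anchor spacing **and** no ambiguous bases in the
window; rejection reasons (`anchor_fail`, `length_fail`,
`ambiguous_base`) are logged per class. These rules are deliberately
conservative and configurable — the original pipeline's criteria are not
public. Profiles report raw count frequencies with no pseudocounts, so the
descriptive output stays faithful; stabilisation happens only inside the
likelihood.

## The boundary estimator

For candidate boundary $b$, the model says: left-junction positions
$\le b$ retain library-derived non-WT bases at rate $q$
(`expected_nonwt`, estimated from the library profile by default, or the
analytic $0.75/P$), all other cells sit at the sequencing error floor $f$.
With per-position non-WT counts $k_i$ of $n_i$ reads,

$$\ell(b) = \sum_{i \le b} \big[\log B(k^L_i; n^L_i, q) + \log B(k^R_i; n^R_i, f)\big]
          + \sum_{i > b} \big[\log B(k^L_i; n^L_i, f) + \log B(k^R_i; n^R_i, q)\big]$$

and $\hat b = \arg\max_b \ell(b)$ over the $P+1$ candidates. Numerical
choices: binomial coefficients are dropped (constant in $b$); a
pseudocount of 0.5 is added to each success and failure cell; rates are
clamped to $[10^{-12}, 1-10^{-12}]$ so an error floor of zero cannot
produce infinite terms; ties within $10^{-8}$ of the maximum resolve to
the smallest $b$ and are reported in the call. The reported confidence is
the log-likelihood gap to the runner-up boundary — an addition of this
package; the original analysis reads the split by inspection and offers no
uncertainty measure. The `error_floor` default is $10^{-3}$; when an
independent error estimate exists (e.g. from non-randomized positions),
pass it instead.

This is a deliberately plain two-rate model: the retained rate is not
corrected for the error process (the $O(qf)$ difference is far below the
resolution of the argmax), and one global $q$ is shared across positions.
Position-specific selection against some mutants shifts retention rates
*downward* on the retained side but does not move the changepoint, which
is what the estimator cares about.

```{r}
jp <- simulate_junction_profiles(spec, boundary = 7, depth = 2000, seed = 1)
infer_boundary(jp)
```

## Sequence stringency

A position that matters for integrase binding purges non-WT bases from the
recombined pool. `stringency_skew()` compares the per-position non-WT
retention on the library-derived side of the junction profiles
(`retained_profile()`) against the neutral 7.5% by an exact two-sided
binomial test, reports the relative skew $(\mathrm{obs}-\mathrm{exp})/\mathrm{exp}$
(0 when neutral, −1 when fully purged), and adds Benjamini–Hochberg
q-values across the P simultaneous tests — the original report is
qualitative, so the correction is added rigor. `stringency_base_skew()`
repeats the test per non-WT base against $q/3$, since base identity can
matter, not just non-WT status.

## Assay statistics

`recombination_frequency()` returns recombinant/total with a Wilson score
interval — chosen over Wald because these assays routinely count 0–3
recombinants, where Wald collapses. Percentages are formatted to 2
significant figures only at the reporting layer; full precision is kept
internally. `fold_change()` propagates a confidence interval on the log
scale with the delta-method standard error and declines to report one when
either count is zero. `profile_summary()` apportions percentages by
largest remainder so they sum to exactly 100 at the reported precision
(49.5/48.5/1/1 from 50/49/1/1 of 101 clones). `adjusted_activity()` is the
transformation-efficiency-normalised count ratio of the non-replicative
circle assay. Replicate-level significance testing across strains is out
of scope: the printed wet-lab frequencies rest on replicate data that is
not published, so only the estimator layer is implemented.

## What a green test establishes — and what it does not

The simulator emulates single-base randomization, reciprocal exchange,
uniform substitution error and filter-detectable read corruption. It does
not emulate PCR amplification bias, indels, quality-score structure,
chimeras that mimic legitimate templates, or biological selection during
library propagation. Boundary-recovery results (e.g. ≥99% recovery at
depth 10,000 and error 0.001 for every true boundary) are therefore
statements about the estimator under the stated noise model, not about
wet-lab performance. Two further limitations are inherited from the
biology: when the crossover region sits in a mononucleotide run (as for
*attC* L-box recombinants in an adenine stretch), exchanges at different
boundaries produce identical products and no estimator can separate them;
and only one crossover event per molecule is modelled.

## Design decisions taken where the design was open

* The bundled site's flanks and exact box coordinates are synthetic
  placeholders, clearly named as such; the published figure with the full
  65-bp site is not machine-readable here, so only the L-box sequence, the
  spacer-adjacent randomized pair and the R-box crossover triplet are
  anchored. The default true boundary is the site's annotated $b = 7$
  (between the L-box-border adenines), and generic examples use other
  boundaries freely.
* Window extraction is offset-based from the left anchor rather than a
  contiguous slice, so non-contiguous windows (the R-box `C` sits apart
  from the L box) cost nothing.
* The CLI (`inst/cli/crossmapr.R`; subcommands `simulate`, `profile`,
  `infer`, `assay`, `e2e`) is a thin wrapper over the exported functions;
  seeds are mandatory in configs for stochastic subcommands, and exit
  codes separate validation errors (2) from data errors (1).
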