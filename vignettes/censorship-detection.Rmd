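---
title: "Sampling operators and censorship detection in deep-sequenced phage-display libraries"
author: "phagecensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling operators and censorship detection in deep-sequenced phage-display libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecensor)
```

## The problem

A phage-display peptide library read out by deep sequencing is, formally, a
multiset: an ordered set of unique sequences $S$ with a copy-number vector
$n = \|n_i\|$, where $n_i \ge 0$ counts the reads of sequence $i$ and the
theoretical diversity $N$ (e.g. $20^7 \approx 1.28 \times 10^9$ for 7-mer
peptides) bounds how many sequences could exist. Copy numbers in real
libraries span six or more orders of magnitude, and every laboratory
manipulation — panning, amplification, sample preparation, sequencing —
changes $n$. Manipulations that treat sequences independently are diagonal
operators on $n$; the most important of them is stochastic **sampling**:
drawing a fraction $f$ of the library's $m = \sum_i n_i$ physical
instances.

Quality filtering of sequencing reads is supposed to be such a neutral
sampling step: if base-calling errors strike reads at random, discarding
low-quality reads is indistinguishable from sampling the library at the
measured fraction $f = \mathrm{sum}(n^{\text{after}}) /
\mathrm{sum}(n^{\text{before}})$. The scientific question this package
answers is: *which sequences lose significantly more reads during
filtering than that null model allows?* Such sequences are **censored** —
their reported abundance is systematically too low, which corrupts any
downstream inference that treats low or zero counts as evidence of
non-binding.

## The sampling operator and its law

`sample_multiset(ms, f)` draws $\mathrm{round}(f\,m)$ instances uniformly
without replacement from the $m$ instances of the library (round-half-to-
even; the choice only matters when $f\,m$ is exactly half-integral). The
resulting count vector $B$ follows the multivariate hypergeometric
distribution; the implementation uses the sequential conditional
decomposition $B_i \mid B_{1..i-1} \sim
\mathrm{Hypergeom}(n_i,\; m_{>i},\; s_i)$ in compiled code, which is exact
and needs no materialisation of the $m$-element instance array. Every draw
is checked against the defining invariants: $\sum_i B_i =
\mathrm{round}(f\,m)$, $0 \le B_i \le n_i$, and no sequence is created
from nothing ($n_i = 0 \Rightarrow B_i = 0$).

Two independent routes validate the sampler in the test suite:

* `enumerate_outcomes()` lists *every* achievable outcome of a small
  multiset with its probability
  $\prod_i \binom{n_i}{B_i} / \binom{m}{\mathrm{round}(f m)}$ by
  brute-force recursion. For the toy multiset
  $\{A(1)\,B(2)\,C(3)\,D(4)\}$ at $f = 0.5$ there are exactly 22
  achievable outcomes, and $10^5$ draws reproduce their frequencies
  (chi-square goodness of fit). Enumeration is guarded (default: at most
  30 total elements) because the number of outcomes grows combinatorially.
* closed-form hypergeometric marginals (`dhyper`/`qhyper`) check each
  element's empirical distribution for multisets too large to enumerate,
  e.g. the sparse dyadic multiset with counts $1, 2, 4, \dots, 64$, whose
  full outcome set (~$1.8 \times 10^5$ vectors) would leave expected cell
  counts far below chi-square validity at any practical number of draws.

Averaging $k$ independent draws converges element-wise to $f \cdot n$ —
repeated sampling "averages out" to a scalar dilution — and the test
suite verifies that the maximum absolute deviation shrinks from
$k = 10^2$ through $10^4$.

## Monte-Carlo confidence bands

`confidence_interval()` summarises $k$ draws per element. Two band
definitions are provided and labelled, because they are *not* the same
thing:

* **minmax** (default, $k = 10{,}000$): $[loC_i, hiC_i]$ = the smallest
  and largest count of element $i$ seen in $k$ iterations. This follows
  the common practice of reporting the envelope of a large simulation.
* **quantile**: empirical $(1-\ell)/2$ and $1-(1-\ell)/2$ quantiles at a
  stated level $\ell$ (default 0.999).

The minmax envelope is easy to compute and interpret, but its coverage is
a property of extremes of finitely many draws: a fresh draw escapes one
element's envelope with probability $\approx 2/(k+1)$ (less for strongly
discrete marginals). Per element that is excellent — about $0.9996$ at
$k = 5{,}000$ — but summed over a library of $10^3$ wide-support elements
it implies that a fresh draw has an appreciable chance (we measure
roughly one in four at $k = 5{,}000$) of escaping the joint band
*somewhere*. Claims that "no solution escaped the envelope of the same
$k$ draws" are circular, and users should not read the minmax band as a
family-wise interval. The quantile method makes the nominal per-element
level explicit; neither method controls the family-wise rate, which is
acceptable here because censorship calls are made per sequence and the
empirical false-positive rate is controlled (below).

Band width for the minmax method is non-decreasing in $k$ by
construction, which the tests assert by extending a common RNG stream.

## Censorship detection

For a filtering step `before -> after`:

1. `measure_fraction()` computes $f = \mathrm{sum}(after) /
   \mathrm{sum}(before)$, erroring if filtering "created" reads.
2. `confidence_interval(before, f, k)` builds the null band: what counts
   random sampling at $f$ would leave.
3. `detect_bias()` classifies every sequence:
   * `undetermined_low_copy` if $n^{before}_i < 10$ (default): for such
     sparse sequences a disappearance cannot be distinguished from
     sampling noise, and the bias factor is fixed at 1;
   * `within_band` if $loC_i \le n^{after}_i \le hiC_i$: bias factor 1;
   * `censored_below` if $n^{after}_i < loC_i$: bias factor
     $B_{ii} = n^{after}_i / (f\, n^{before}_i)$, the sequence's
     survival ratio relative to neutral sampling (fold-loss $1/B_{ii}$);
   * `above_band` if $n^{after}_i > hiC_i$: reported as a diagnostic with
     bias factor 1 — the multiplicative bias is defined only for the
     censored direction, and when censorship removes mass from the
     library the measured $f$ drops slightly below the survival rate of
     unaffected sequences, which then sit high against the band.
4. `censored_table()` ranks censored sequences by ascending $B_{ii}$
   (ties: larger pre-filtering count first, then lexicographic), with
   peptide translations, expected counts and fold-losses.

Detection operates on DNA-level multisets: censorship is hypothesised to
be nucleotide-sequence-specific, so aggregating synonymous codons first
would dilute the signal.

## The synthetic-data generator

`generate_library()` + `generate_fastq()` produce a fully ground-truthed
experiment; all defaults were chosen once, as the study conditions, and
are documented here:

* unbiased copy numbers log-uniform on $[1, 10^4]$ (continuous
  multi-decade abundance range); ramp ($1..n$) and explicit laws are
  available for the classical test multisets;
* censored sequences: copy numbers log-uniform on $[100, 10^4]$, planted
  survival factors $B$ log-uniform on $[0.01, 0.2]$ (5- to 100-fold
  loss), each with 3–4 fixed "cluster" positions inside its 33-nt
  window — mimicking the observation that censored sequences harbour
  low-quality calls at a few recurrent sites;
* reads are `upstream + 21-nt insert + 12-nt GGGS tail`, all positions at
  Phred 35; an instance of a censored sequence has its cluster positions
  degraded with probability $1 - B$; every read independently suffers one
  random degraded window position with probability 0.1 (so a min-Phred-13
  filter removes ~10% of reads, the background the fraction-measurement
  is built on); degraded scores are uniform on $1..12$ — below the
  censoring cutoff but above zero, so the permissive min-Phred-1 library
  retains every read;
* a configurable fraction of reads get one upstream-adapter mismatch;
  these are recognised (edit distance ≤ 1) and counted as flawed at
  ingest but never used, since flawed-adapter reads carry elevated error
  rates in real data.

Under min-Phred filtering at the cutoff, a planted sequence's expected
survival is exactly $B \times (1 - \text{background})$, so the planted
$B$ is the quantity `detect_bias()` should recover.
`simulate_quality_filtering()` is the same model marginalised over reads
(per-sequence Binomial survival); it is used where materialising millions
of FASTQ records would add nothing, and its equivalence to the FASTQ
path is itself tested at small scale.

What the generator deliberately does **not** emulate: PCR point
mutations, AT-bias of gel purification, growth bias, barcode
demultiplexing, paired-end structure, or any mechanistic model of *why*
the sequencer censors — only the observable consequence (recurrent
low-quality sites on specific sequences) is modelled. Passing tests
therefore demonstrate that the statistical machinery recovers planted
censorship of this form, not that real Illumina censorship has this
mechanism.

## Quality filtering semantics

* "Cumulative score" filtering thresholds the *product* of per-base
  accuracies $\prod_j (1 - 10^{-Q_j/10})$ over the 33-nt window (not a
  raw sum of Phred scores), matching the worked accuracy arithmetic
  $0.95^{33} \approx 0.18$ and $(1)^{27}(0.95)^5 = 0.77$.
* The min-Phred-1 library keeps reads with $\min_j Q_j \ge 1$, i.e.
  discards reads containing a Phred-0 call ("< 1" and "contains 0"
  coincide for integer scores).
* Filtering considers only the 33-nt analysis window, not the full read.

## Numerical choices and problem sizes

* Sample size $\mathrm{round}(f m)$ with banker's rounding; seeds are
  ordinary `set.seed()` integers and every stochastic function accepts
  one, making draws bit-reproducible.
* The band summaries store per-element tallies (length $m + N$) instead
  of a $k \times N$ draw matrix, so $k = 10^4$ iterations over a
  multi-million-read library fit comfortably in memory.
* Test and validation runs use a 1000-element ramp library (500,500
  reads), a 5,050-sequence log-uniform library (~5.5 M reads) for the
  planted-censorship study, and a ~20,000-read FASTQ for the end-to-end
  integration test; these sizes give the statistics room to concentrate
  while keeping the whole suite fast.
* The bias estimator $\hat B = n^{after}_i/(f n^{before}_i)$ has
  binomial relative standard deviation $\approx 1/\sqrt{f B n_i}$: for
  $B = 0.01$ even a few thousand pre-filter copies leave only tens of
  surviving reads, so individual $\hat B$ values for strongly censored,
  moderately abundant sequences should be read with error bars of that
  order. *Detection* (the flag) is far more robust than *estimation*
  (the factor).

## Known limitations

* The minmax band's family-wise coverage caveat above.
* Flawed-adapter reads are counted, never rescued; libraries dominated by
  adapter damage will look smaller than they are.
* No correction of censored counts is attempted: the package quantifies
  the bias factor but deliberately stops short of re-inflating counts.
* Peptide-level views are derived by translation after DNA-level
  analysis; synonymous-codon aggregation before detection is not
  offered.
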