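---
title: "Methods: comparative tRNAome statistics, code combinatorics and wobble stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative tRNAome statistics, code combinatorics and wobble stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaome)
```

## The scientific problem

A species' complete set of tRNA genes -- its *tRNAome* -- carries a fossil
record of how the genetic code grew.  When a tRNA gene duplicates and the
copy acquires a new anticodon, the two genes start out nearly identical
(often a single base apart) and then diverge.  Comparing how far
*alloacceptor* tRNAs (genes charging different amino acids) have separated
therefore gauges how recently a tRNAome's gene family expanded: lineages in
which alloacceptor genes remain strikingly similar look "primitive" in the
sense of sitting close to the duplication events that built the code.  The
same duplication logic shows up in anticodon usage per codon box (wobble
stages), in the combinatorial pruning of alternate genetic codes, and in
the contiguity of codon domains of biosynthetically related amino acids.
This package implements those computations end-to-end and ships a seeded
simulator so that every stage is testable without external genome data.

## Gene labels and strand conventions

Comparative tRNA figures name genes by their **complementary codon**:
`LeuCTC` is the leucine tRNA that *reads* codon `CUC`, via anticodon `GAG`.
The package stores the anticodon internally and derives the complementary
codon by reverse complement (`complementary_codon()`), rendering and
parsing figure-style labels (`gene_label()`, `parse_gene_label()`).  This
removes a chronic off-by-strand ambiguity while keeping both conventions
accessible.  Internally the DNA alphabet (`T`) is canonical, because gene
names use it; RNA input is accepted and mapped.  Code tables, by contrast,
are RNA-style (`U`), with explicit converters (`codon_rna()`,
`codon_dna()`) and no silent coercion.

## Base-difference statistics

The pairwise statistic delta is defined as the **unit-cost global
alignment (Levenshtein) distance**: substitutions, insertions and deletions
each cost 1.  Aligned figures in the comparative literature do not state an
aligner; unit-cost global alignment is the minimal choice that (a) reduces
to the Hamming count for equal-length sequences in register, reproducing
the delta = 1 duplication signature, and (b) handles the length
heterogeneity of serine and leucine tRNAs (variable arm).  Normalization
divides by the optimal alignment length, giving distances in [0, 1].  Ties
among co-optimal alignments are broken deterministically -- substitution
over gap, then gap in the first sequence over gap in the second -- which
fixes the column layout used by `region_delta()` (1-based inclusive
intervals on alignment columns; a convenience `"anticodon_loop"` region is
available when the anticodon position is annotated).  Because alignment is
strand-literal, normalized distance is *not* claimed invariant under
reverse-complementing both sequences.

`d_allo()` averages normalized distances over **all** alloacceptor gene
pairs rather than one representative per amino acid; gene copies
(`copy_index > 1`) are excluded by default so copy number does not weight
the mean (`include_copies = TRUE` restores them).  The analogous
isoacceptor mean is reported alongside.  Published per-species index values
(0.351--0.600 for archaeal exemplars) depend on genome-derived gene sets
and protocol details that are not restated anywhere; they serve as external
calibration for the expected range, not as test targets.  Group means of
*raw* delta (e.g. per-domain Asp/Glu pair averages) use per-column edit
counts, i.e. a k-column gap contributes k, since the alternative
(gap-as-single-event) is nowhere specified.

## Fitch--Margoliash trees

`fit_tree()` minimizes the weighted least-squares criterion
$\sum_{i<j} w_{ij}\,(d_{ij} - p_{ij})^2$ with the classic weights
$w_{ij} = 1/d_{ij}^2$, where $p_{ij}$ is the leaf-to-leaf path length.
Zero distances (identical gene copies) would give infinite weight; they
take the weight of the smallest nonzero distance instead.  Branch lengths
for a fixed topology are solved by non-negative least squares
(`pracma::lsqnonneg` on the pair-by-edge incidence matrix), matching the
non-negativity default of classic implementations.  Topology search is
stepwise addition in input order followed by greedy nearest-neighbour
interchange to a local optimum.  Exactness is claimed -- and tested by
exhaustive enumeration over all topologies -- for instances up to five
taxa, and additive matrices of any tested size are recovered with zero
residual and exact branch lengths.  The trees analysed here have at most a
few dozen leaves, for which NNI local optima support the qualitative
claims tested (sisterhood of duplication pairs, per-species segregation);
global rearrangement search and bootstrap support are out of scope, and
trees are reported unrooted.  `cluster_tightness()` calls a leaf group
monophyletic in the unrooted sense when some branch splits exactly that
group from the rest.

Newick output is canonicalised: the serialization re-roots at the internal
node adjacent to the lexicographically smallest leaf and orders children by
their subtree's smallest label, so isomorphic trees with equal branch
lengths serialize byte-identically.

## Code tables, chemical distance and contiguity

`classify_boxes()` partitions the 64 codons into 16 boxes by their first
two bases: a box is `1aa` when all four codons encode one amino acid and
`2aa-standard` when they split 2+2 with no stops; the standard code yields
8 + 5 = 13 standard boxes and 3 other boxes.  The phase table records the
10/10 split between prebiotically sourced (Phase 1) and biosynthetically
derived (Phase 2) amino acids, with Pro/Thr and Phe/Tyr flagged borderline
(annotation only -- phase stays binary).  Chemical distances are the
Grantham (1974) composition/polarity/volume constants, embedded as package
data because the source analyses cite individual values (maximum 215 for
Cys-Trp, minimum 5 for Leu-Ile) but not the matrix.

The **contiguity statistic** formalizes "enriched contiguities" between
codon domains of biosynthetically related amino acids.  A precursor-product
pair is contiguous when their codon domains contain codons one base apart.
The null model permutes amino-acid labels over the code's *fixed*
codon-domain partition (stop codons excluded), the standard construction
for code-randomization arguments, with an add-one permutation p-value.
This numeric formalization is the package's own: the source describes the
enrichment qualitatively.  The default pair list keeps the conversions
whose members are both canonically encoded (Ser-Cys, Ser-Trp, Asp-Asn,
Glu-Gln); tRNA-dependent conversions involving Sec, Sep and fMet stay in
the phase table as annotations because they own no codon domains among the
20.  Self-pairs are contiguous by definition and dropped with a warning.

```{r contiguity}
ct <- contiguity_statistic(n_perm = 999, seed = 1)
ct$observed
signif(ct$p_value, 2)
```

## Exact code-space combinatorics

The reception-seating model counts $p!\,(q!)^p$ arrangements of $pq$
guests in $p$ sections of $q$.  One section of 20 gives
$20! \approx 2.4\times10^{18}$; five sections of four give
$955{,}514{,}880 \approx 9.6\times10^{8}$; the ratio, rendered at one
significant figure, is $4\times10^{-10}$.  These counts exceed the
$2^{53}$ exact range of doubles and no arbitrary-precision package is part
of this stack, so the package carries a small exact big-integer layer
(base-$10^4$ digit vectors; add, multiply, power, factorial, and
Pascal-rule binomials so no big-integer division is ever needed).
Scientific-notation rendering is presentation-only; the exact digits are
preserved.  Selection factors that are exact powers of ten times small
integer mantissas multiply exactly in (mantissa, exponent) form:
$10^{-11} \times 10^{-6} \times 4\times10^{-4} = 4\times10^{-21}$.

`packet_allocation_count()` counts assignments of distinct codons to
distinct amino acids with per-amino-acid packet-size bounds by the
recursion $f(c,a) = \sum_s \binom{c}{s} f(c-s,\,a-1)$.  This is an
**exploratory** counter: for 64 codons, 20 amino acids and packets of 1--6
it yields about $3.7\times10^{82}$, far above the published
order-of-magnitude figure of $2\times10^{19}$, whose underlying
reception-seating counting model (whether codons are interchangeable,
whether packets must be box-contiguous) is specified only in earlier work
and is not reproduced here.  The discrepancy is expected and documented;
the printed $2\times10^{19}$ and $2\times10^{8}$ values are carried as
inputs to the reduction-factor bookkeeping, not recomputed.  Infeasible
packet bounds raise an error rather than returning zero, to catch
configuration mistakes.

## Wobble stages

Each standard codon box is staged by the set of first-anticodon-base
classes present among the tRNAs reading it: `{U}` is Stage I (the
superwobble single anticodon), `{G,U}` Stage II (the anticodon-duo of the
most primitive extant usage), `{G,U,C}` Stage III, and any set containing
`A` is Stage IV (A read as A/I, inosine assumed at position 34 -- no
chemical verification is attempted).  Stage V (secondary single-UNN
simplification in organelles and reduced genomes) is sequence-identical to
Stage I, so an `organelle_hint` flag disambiguates; without it the box is
reported `I/V-ambiguous`.  Non-standard boxes (stop-containing and the
3+1 Ile/Met box) are excluded from staging and reported descriptively.
Mixed-stage organisms are summarized by their per-box distribution plus
the modal stage rather than forced into one label; a uniform Stage II
profile across all 13 standard boxes earns the "Mka-like primitive
Archaea" label.  Staging is invariant to gene copy number, and the stage
index is monotone: adding an anticodon class to a box never lowers its
stage.

## Metabolic-expansion dynamics

The enrichment of functional RNA by metabolite-driven replicator induction
is modelled by the autonomous logistic-form ODE
$dR/dt = k\,\alpha\,R\,(1 - R + \sigma)$ -- the only reading of the
integral form consistent with a monotonic rise.  All quantities are
dimensionless; no chemical calibration is implied and none is published.
$K = 1+\sigma$ is the stable fixed point, $R=0$ unstable, so any
$0 < R_0 < K$ rises monotonically to dominance.  Integration uses
fixed-step 4th-order Runge-Kutta (`deSolve`), with the step auto-halved
until the trajectory matches the analytic solution
$R(t) = K R_0 /\big((K-R_0)e^{-k\alpha K t} + R_0\big)$ (evaluated in the
overflow-safe $e^{-rt}$ form) to $10^{-6}$ relative error.  The closed
form doubles as the test oracle; a stochastic birth-process variant is
deliberately out of scope.

```{r reim}
p <- reim_params(k = 1, alpha = 1, sigma = 0, R0 = 0.01, t_end = 20)
s <- reim_simulate(p)
c(final_R = s$final_R, t95 = s$t95)
```

## What the generator emulates -- and what it does not

`generate_trnaome()` implements a cluster-dispersion caricature of tRNAome
growth: one ancestral 72-nt sequence drawn with per-position GC
probability 0.7 (defaults follow canonical tRNA gene length and the
GC-rich sequence-space origin of the model; the anticodon sits at
positions 34--36), a cascade of duplication events that rewrite the
anticodon window and optionally add substitutions, then per-gene
background substitutions, Poisson with mean `background_sub_rate x depth`.
Substitutions are uniform over non-anticodon positions with the
replacement base uniform over the three alternatives; there is no
transition/transversion bias (none is published for this setting) and no
indels by default, so generated families are fixed-length and anticodon
identities are exact by construction.  The default genealogy is six genes
in four amino-acid families, including a 0-substitution duplication that
reproduces the delta = 1 signature.  `generate_domain_contrast()` grows
one genealogy per species and lays background divergence on top twice
(default depths 2 and 20, a 10x substitution-budget contrast at rate 1
substitution per gene per depth unit), emulating primitive versus
long-diverged lineages.

Passing tests on these synthetics shows the *pipeline* recovers the
structure the generator put in -- duplication sisters, depth ordering of
the alloacceptor index, wobble ensembles.  It does not show that real
tRNAomes evolve by this model: real genes have introns, modified
nucleosides, structure-constrained substitution patterns, variable-length
arms and horizontal transfer, none of which are simulated.  Published
per-species index values therefore cannot be reproduced from synthetic
data and are not claimed.

## Numerical choices and degenerate inputs

* Alignment tie-breaks and Newick canonicalisation are deterministic, so
  equal inputs give byte-identical outputs everywhere.
* FM fitting clamps branch lengths at zero via non-negative least squares
  re-solving, and caps zero-distance weights as described.
* The RK4 step is halved at most 12 times before the integrator reports
  failure rather than returning an inaccurate trajectory.
* Empty FASTA files yield an empty collection with a warning; malformed
  headers and non-nucleotide characters fail loudly, naming the record.
* Duplicate-identity genes are kept and disambiguated by `copy_index`
  (real tRNAomes have copies); unknown header dialects fail rather than
  guess.
* The spliced/unspliced status of intron-containing input genes is not
  resolved; sequences are analysed as given.

Test problem sizes were chosen at desk scale: the edit-distance oracle
checks 200 random pairs against an independent dynamic-programming
implementation; the tree oracle enumerates all topologies for 30
four-taxon and 10 five-taxon grid-valued metric matrices; the
depth-contrast recovery runs 20 seeded replicates; the packet-allocation
counter is verified against exhaustive enumeration for up to 8 codons and
4 amino acids.

## Known limitations

Only pairwise alignment is implemented (no MSA, no structure-aware
alignment); tree search is heuristic beyond five taxa; the contiguity
null and the packet counter are the package's own formalizations of
verbally described constructions; wobble staging ignores nucleoside
modification chemistry; and the simulator's realism limits are described
above.
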