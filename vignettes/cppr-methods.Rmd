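---
title: "Designing and validating cPPR proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating cPPR proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprkit)
```

## The recognition model

A pentatricopeptide-repeat (PPR) solenoid reads single-stranded
nucleic acid with one 35-amino-acid repeat per base. Two repeat-local
positions carry the specificity: position 5 hydrogen-bonds the
Watson–Crick face of the base directly, and position 35 contacts
purines directly and pyrimidines through water. The canonical code is
(T,N)→A, (T,D)→G, (N,D)→T/U, (N,S)→C. Everything else in the repeat is
structural and identical between repeats in a consensus design.

Two modelling commitments follow:

* **U ≡ T.** The same residue pairs bind RNA and ssDNA, and the
  thymine methyl points away from the protein, so the code table does
  not distinguish the two. All internal logic is in DNA alphabet; an
  `rna` flag restores `U` on display. The code is identity-only: it
  does not model the substantial affinity difference between poly(U)
  and poly(T) tracts, which arises from stacking/hydration effects
  outside a per-base code.
* **Unknown pairs are wildcards.** `base_for_residues()` returns `N`
  for pairs outside the table instead of erroring, so natural PPR
  arrays with non-canonical codes can still be parsed and scanned;
  `N` matches every base at zero cost in mismatch scoring.

The code table is data (`inst/extdata/ppr_code.tsv`), validated on
load: the four canonical entries must be present and no residue pair
may map to two bases.

## The consensus scaffold

A design is `N-cap + R × repeat + solvating helix`, with defaults
`MGNS` and `VTYTTLISGLGKAG`. Repeat 1 (N-terminal) reads the 5'-most
target base; this polarity is fixed by the co-crystal geometry of a
10-repeat telomere binder on `TTAGGGTTAG`, whose repeats read
T,T,A,G,G,G,T,T,A,G in N→C order. The residue arithmetic
`global = cap_len + 35·(r−1) + p` maps repeat-local to global
coordinates and is anchored by the standardised annotation
(Arg16 of repeat 5 = Arg160, Lys28 of repeat 4 = Lys137, Glu19 of
repeat 9 = Glu303 with the 4-residue cap). One published legend maps
Glu170/Glu205/Glu240 to "Glu29"; the same arithmetic that fits every
other anchor places them at local position 26, consistent with the
described Lys28–Glu26 network, so the package follows the arithmetic
and does not renumber.

The default 35-aa template is
`VVTYTTLISGLGKAGRLEEALELFEEMKEKGIVPD` with variable slots at positions
5 and 35. Only a subset of its positions is pinned by direct
structural evidence (2=V, 13=K, 16=R, 18=E, 19=E, 25=E, 26=E, 28=K);
the rest follow the consensus logic in which the C-terminal solvating
helix repeats the first helix of the consensus repeat (the template's
residues 2–15 are exactly the default helix). Templates are config
files, so an alternative consensus can be supplied without code
changes; validation enforces length 35 and the pinned positions.

`parse_design()` (the inverse operation) tolerates up to 20% mismatch
at non-variable positions per repeat by default, so variant scaffolds
parse while frame-shifted decompositions fail loudly with the residual
length.

```{r design}
telo1 <- build_design("TTAGGGTTAG", name = "cPPR-Telo1")
telo1
parse_design(telo1)
```

## Scanning and telomere annotation

Scanning is exhaustive Hamming-distance matching over all
`len − L + 1` windows, with `N` free, ties broken by offset, and
0-based half-open coordinates in machine output (unambiguous interval
arithmetic; 1-based numbers appear only in prose). ssDNA has no
strand, so reverse-complement scanning is an explicit opt-in for
double-stranded inputs. Mismatches are unweighted: terminal target
positions are known to contribute least to affinity, but no published
weights exist, so the default stays uniform with an optional future
weighting left out rather than invented.

`annotate_telomeric_primer()` splits a primer into a 5' spacer and the
longest 3' suffix that is a substring of the infinitely repeated unit.
A minimum reported segment of one unit length (default 6 nt for
`TTAGGG`) keeps chance matches of one or two trailing bases from
counting as telomeric; `min_len = 1` restores the literal rule. The
G-quadruplex flag is the standard consensus — four runs of ≥3 G with
loops of 1–7 nt — recorded here because G4 folding competes with
protein binding on telomeric G-strands.

```{r annotate}
annotate_telomeric_primer("CTAGACCTGTCATCATTAGGGTTAGGGTTAGGG")
```

## Bind-n-Seq analysis

The analysis consumes merged reads (paired-end merging is upstream and
out of scope). Trimming is anchored — the 5' flank must match at the
read start and the 3' flank at the read end, each within 1
substitution by default (the anchored equivalent of two-pass adapter
trimming on this construct) — and only inserts of exactly the designed
length (10 nt) survive; all failures are tallied, never raised.

Enrichment replaces regular-expression motif elicitation (DREME) with
exact k-mer tests: every k-mer occurring in the selected pool gets a
one-sided hypergeometric tail p-value against the background pool
(counts are sliding-window occurrences; totals are window counts) and
a Bonferroni-style E-value `p × #k-mers tested`. This is a stated
simplification: the headline property — the designed target is the
most enriched 10-mer — is testable without reimplementing a heuristic
regex search, and exact words keep the null distribution exact. Zero
background counts need no pseudocount; the hypergeometric handles
them natively. Logo heights are the per-position information content
`2 + Σ_b f_b log2 f_b` bits.

## The synthetic selection model

The simulator generates the two statistical features the analysis
relies on and nothing more: a uniform i.i.d. background library, and a
selected pool in which an insert at Hamming distance *m* from the
design target is retained with probability ε^m. This is the simplest
monotone model consistent with binding degrading over a 1 → 3 → 5
mismatch series; it does not attempt to fit measured affinities,
position-specific weights (real terminal positions matter less), PCR
bias, duplicates, or indel errors (substitution-only read errors keep
anchored trimming honest). Defaults are ε = 0.3 and 20,000 reads per
pool — a selection stringency that leaves the per-position predicted
base at frequency 1/(1+3ε) ≈ 0.53 against a 0.25 background, and a
depth at which the exact target (expected count ≈ n·(1+3ε)⁻¹⁰·…,
≈ 30 reads) dominates the ranking; sequencing depth of the original
libraries is unpublished, so the default is a realistic MiSeq-scale
choice made once. Passing the recovery test shows the pipeline's
inference is correct under this model; it does not certify performance
on real libraries with correlated errors or amplification structure.

Under ε^m retention the expected acceptance rate of a uniform insert
is `((1+3ε)/4)^L ≈ 5.8×10⁻⁴` for L = 10, so `simulate_bindnseq()`
decides retention on the integer base matrix and only materialises
surviving strings; all generators seed the RNG locally and restore the
caller's state, so results are bit-reproducible per (seed, parameters)
without side effects.

## Structural metrics

`read_structure()` parses PDB coordinates (via bio3d), resolves
alternate locations by highest occupancy with alphabetical label as
the deterministic tie-break, and classifies residues
protein/DNA/water/other by standard name sets. Atom counts are heavy
atoms per class after altloc resolution — the quantity refinement
tables report.

Hydrogen bonds use a heavy-atom N/O donor–acceptor distance criterion
only, default 3.5 Å and configurable to 4.0 Å (the threonine–adenine
contacts of PPR repeats run 3.6–3.9 Å); no angle term is possible
because deposited models at ~2 Å lack hydrogens. Pairs within one
residue or below 2.2 Å (covalent range) are excluded.

The junction network tracks, for each of the R−1 inter-repeat
junctions, three side-chain contacts of the convex-face b helices:
Arg16–Glu19 within the following repeat, Arg16 to the preceding
repeat's Glu18, and Lys28 to the following repeat's Glu26. Missing or
substituted residues make a junction *indeterminate* (NA), which
`compare_networks()` excludes and reports rather than counting as
absent. The apo→bound comparison counts junctions whose Arg16–Glu19
bond is present apo and lost bound — the switch (the glutamate turning
to its own main chain) that opens the convex face as the solenoid
wraps its target; in the deposited telomere-binder pair this happens
at three of nine junctions, alongside loss of the Lys28–Glu26
cross-repeat bonds.

Superhelix length is defined here as the maximum pairwise Cα–Cα
distance — the published compaction (104 Å apo → 64 Å bound) does not
state its measurement convention, so this package records its own
convention with every result and treats ±5 Å as the meaningful
resolution of the comparison.

Because deposited coordinate files cannot be bundled, the test suite
exercises these operations on synthetic solenoid models
(`synthetic_solenoid_pair()`): idealised coordinate files carrying the
tracked residues, junction bonds placed in or out of range, and exact
Cα extents. They are labelled synthetic throughout; users with the
deposited apo/bound pair can run the identical pipeline on it via
`fetch_structure()` or local files.

```{r structures}
p <- synthetic_solenoid_pair(tempdir())
apo <- read_structure(p$apo); bound <- read_structure(p$bound)
compare_networks(junction_networks(apo, 10), junction_networks(bound, 10))
c(apo = superhelix_length(apo), bound = superhelix_length(bound))
```

## Numerical and testing choices

* Exact tests: `phyper()` tails; the test suite checks them against an
  independent `choose()`-based enumeration on all tables with totals
  ≤ 12 and against one-sided `fisher.test()` on larger random tables.
* Scanning, hydrogen-bond detection and Hamming scoring are each
  verified against brute-force re-implementations in the tests.
* Problem sizes in the suite: full 20,000-read pools for the recovery
  check (seconds at the matrix-based sampler), 100,000 inserts for
  uniformity bounds, ≤ 500 atoms for oracle-checked structure models —
  sizes chosen to make the statistical assertions sharp at desk scale.
* Degenerate inputs: empty targets, non-decomposable protein lengths,
  mixed-length insert pools, sub-design-length subjects (warning +
  empty result, not an error), and absent junction residues all have
  defined behaviour tested explicitly.

## Known limitations

* The recognition code is identity-only: no affinity prediction, no
  RNA/DNA discrimination, no extended probabilistic codes.
* k-mer enrichment finds exact words; degenerate motifs that would
  aggregate related words are out of scope by design.
* The selection simulator is a single-parameter caricature of bead
  selection; conclusions about real Bind-n-Seq libraries require real
  reads.
* Water-mediated hydrogen bonds (pyrimidine recognition at position
  35 runs through water) are not classified as direct bonds and are
  not inferred.
* The superhelix length convention may differ by a few Å from other
  reasonable conventions (helix-axis arc length, end-cap distances).
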