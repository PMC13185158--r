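---
title: "Methods: reference-anchored variant mining and assay quantification"
author: "rhlBminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored variant mining and assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhlBminer)
```

# Scope and model

`rhlBminer` treats variant discovery as a *reference-anchored* problem:
every repository member is interpreted as the reference CDS plus a set of
single-position substitutions (indels are tolerated but treated as
second-class, see below). This is appropriate for intraspecific
repositories at 95–99.2 % identity, where alignment is essentially trivial
and the interesting signal is *which* positions change, *how* (transition
vs transversion, silent vs missense), and *where* (active domains,
binding-site neighbourhoods). It is not a general-purpose variant caller:
there is no quality model, no multi-allele handling, and positions are
CDS-relative, not genomic.

## Coordinates and conventions

All coordinates are 1-based with closed intervals, matching the residue
notation (p260, p305–308) used in the structural literature the fixtures
transcribe. Reports use 60-nt lines, so "line 3" always means reference
positions 121–180.

# Mutation profiling

For equal-length sequences the profile is a position-by-position
comparison. For unequal lengths the pair is first globally aligned and
gap columns are excluded from the *comparable* positions; the identity
percentage is `100 × matches / comparable`, i.e. the denominator excludes
gap columns. The quantity called "percent homology" in the mining
literature is rarely defined precisely; this convention is the most common
one and is what the similarity filters consume.

Codon effects are computed in the reference frame: the alternative codon
is the reference codon with the query's projected bases substituted in.
A gap run whose length is not a multiple of 3 destroys the frame, so
codon effects at and beyond the first frame-breaking gap are reported as
`"ambiguous"` rather than guessed. Ambiguity bases (`N`) are accepted on
input; any mutation involving `N` is classed `"ambiguous"` and excluded
from transition/transversion and base-preference tallies, since the
change class is unknowable.

The translation uses the standard genetic code with the first codon
translated literally (no bacterial start-codon special-casing): every
in-scope comparison is reference-anchored, so any systematic start-codon
convention would cancel out of the comparison anyway.

# Repository filters

Rules are applied per member in a fixed order, and the first matching rule
is recorded: similarity (identity strictly above 99 % or strictly below
75 % — boundary values are kept, because the thresholds are quoted as
strict inequalities), then premature stop codons, then exact duplicates at
the nucleotide level and at the level of the translation up to the first
stop. The source procedure does not state whether duplicate removal
preceded or followed the similarity filter; fixing the order makes the
report deterministic and the filter idempotent, which the tests assert.
Protein-level duplicate detection truncates at the first stop because all
downstream protein analysis operates on the expressed product. The
reference is not a member and can never be removed.

# Hotspots and mismatch motifs

A hotspot is one exact change `(position, substituted base)` carried by at
least `minShare` distinct sequences; the default 4 follows the quoted
"shared by ≥ 4 sequences" literally, and only silent or missense calls
vote (nonsense carriers are removed upstream anyway). Keying on the exact
substituted base means 2 + 2 sequences with different alternates at one
position do *not* form a hotspot; both readings of "shared" are
recoverable from the profile table, but the exact-change reading is the
one that supports downstream "same mutation" reasoning.

A motif is a canonicalized group of nearby substitutions: per sequence,
mutated positions are grouped greedily left to right, extending a group
while the next gap is ≤ `maxGap` (default 4 nt, covering the quoted
"distances of two to four nucleotides") and the span stays ≤ `maxSpan`
(default 10 nt, bounding enumeration; the longest quoted motif spans less).
Greedy extension is a deliberate resolution of an ambiguity: when a chain
of close substitutions exceeds the span bound there is no canonical
split, and the greedy rule is deterministic and order-independent across
runs. Motif identity is `(offsets from the leftmost member, substituted
bases)` only — reference context is not part of the key, because the
motifs of interest are described by what was substituted and how it is
spaced. The default support threshold 5 reads "> 4 sequences" strictly.
Two support counters are reported (same reference start vs anywhere)
because the source wording admits either reading; filtering uses the
any-site counter.

# Global alignment

The Needleman–Wunsch implementation (Rcpp, Gotoh three-state recurrence)
scores with a user-supplied symmetric substitution matrix; the default is
match +1 / mismatch −3, mirroring the discontinuous-MEGABLAST ratio used
to seed repository searches, with linear gaps at −2 (the gap model is not
stated in the source; −2 sits between match and mismatch and is
configurable, including a full affine `gapOpen`/`gapExtend` split). A gap
of length L costs `gapOpen + (L−1)·gapExtend`, so equal penalties give the
linear model. Traceback ties are resolved deterministically
(diagonal > up > left between states; within a gap state, extension is
preferred on ties so that equal-scoring optima keep gaps contiguous —
without this, a 3-nt deletion can legally come back as three 1-nt gaps
and spuriously flag a frameshift). Correctness is checked two independent
ways: exhaustive enumeration of all alignments for short strings, and
`Biostrings::pairwiseAlignment` under the same scoring scheme for longer
ones.

# Protein-level analysis

Substitutions between equal-length proteins are mapped onto annotation
intervals with precedence helix/sheet > turn > loop > "primary". The
precedence is an artifact decision (overlaps across categories are legal
in the annotation schema and the source does not rank them); it puts the
more specific, geometry-constraining elements first. Physicochemical
deltas use the Kyte–Doolittle hydropathy scale, integer side-chain
charges at pH 7 (D/E = −1, K/R = +1, H = 0 by default and configurable,
since the protonation state of histidine at pH 7 is genuinely ambiguous)
and four polarity classes (nonpolar, polar, acidic, basic).

## Charge patterning (FCR, NCPR, κ)

For a charge sequence, `FCR = (n⁺+n⁻)/N` and `NCPR = (n⁺−n⁻)/N`. The
segregation parameter κ follows the Das–Pappu construction: over sliding
blobs of g ∈ {5, 6} residues, the blob charge asymmetry
`σ = NCPR²/FCR` (0 where FCR = 0) is compared with the sequence value,
`δ_g = mean((σ_blob − σ_seq)²)`, and each `δ_g` is normalized by the same
quantity for a maximally segregated arrangement of the identical
composition; the two normalized values are averaged.

The normalizer deserves care. The textbook arrangement — all negatives,
then neutrals, then positives — does *not* always maximize δ: sliding
blobs cover a terminal residue g times fewer than an interior one, so for
compositions with very few charges an interior placement produces a
larger δ and the naive ratio exceeds 1. κ is therefore normalized by the
maximum δ over a family of ten segregated block arrangements (charge
blocks with the neutral block outside, between, around, or splitting
them, in both block orders so the family is closed under reversal and
global charge swap — which keeps κ exactly invariant under both
symmetries). The family is still an approximation to the factorially
large permutation space, so the ratio is finally truncated at 1 and
flagged `"clamped"` when truncation fires; in practice this happens only
for degenerate compositions (a handful of charges in a short sequence),
never for natural 400-residue enzymes with FCR ≈ 0.2. A terminal `*`
from a CDS translation is stripped; sequences with no charged residues
report κ = 0 with a flag rather than an error.

## Binding-site proximity

Binding sites enter as configuration data (a transcription of published
docking and motif-search residue sets ships in
`inst/extdata/rhlb_binding_sites.tsv`); nothing structural is recomputed.
The proximity code of a substitution with respect to a ligand class is
−1 on a site residue, −(d+1) at distance 1 ≤ d ≤ window, else 0. This
mapping makes the 3-residue energy-nucleotide window span codes −2…−4,
which is exactly how the published heatmap legend reads, and it makes "at
3 residues from the site" map to −4. Substrate sites use a 5-residue
window per the stated methods; the results narrative elsewhere says
"within a three-amino-acid distance", so the window is a parameter and
both values are recorded in the output metadata. Only substrate (sugar
and lipid) on-site hits exclude a sequence as potentially dysfunctional;
product (M-RL) sites are carried for context and never trigger exclusion,
since they were explicitly dropped as selection parameters. Domain A/B
boundaries in the annotation fixture are only known graphically and are
marked approximate, user-editable.

Candidate ranking is deterministic: non-excluded first, then count of
binding-site-adjacent substitutions (desc), hotspot overlap (desc),
identity (asc — at equal evidence the more divergent sequence adds more
information to the next cycle), id (stable tie-break).

# Assay quantification

The standard curve is an ordinary least-squares fit of absorbance on
concentration, requiring ≥ 3 distinct standards. σ in `LOD = 3.3·σ/S` is
the regression residual standard deviation (n−2 denominator) by default —
the source says only "standard deviation of the response" — with a
blank-replicate σ accepted as an option; the printed operating point
(S = 0.0009, σ = 0.0024) then reproduces LOD = 8.8 µg/mL exactly. MAPE is
computed on back-predicted standards. Inverted concentrations below the
LOD are censored (`"<LOD"` in reports); values above the standards' range
are flagged extrapolated but returned. Fold change exposes the rounding
mode explicitly (`round` vs `truncate`) because published fold values mix
the two conventions (2.76 rounds; 1.22 truncates). The contact angle is
the spherical-cap formula `θ = 2·arctan(H/R)` in degrees.

# Synthetic data: what it emulates, and what it does not

The generator's defaults are the study conditions of the mined
repository: a 1,281-nt reference (426 residues + stop) at GC 67.9 %
(within the observed 66–69 % band), variants at 95–99.2 % identity,
substituted bases biased G/C (70 %) with A rarest (5 %), and a silent
fraction of 0.77 (the documented variant profile with 37 of 48 changes
silent). Mutation counts are derived from target identity as
`n = round((1−identity)·L)` — satisfied by construction, not by rejection
sampling. Silent changes are synonymous single-base codon edits, missense
ones non-synonymous non-stop edits, one edited codon per mutation;
internal stops are never created unless the dedicated `stopInjection`
flag asks for filterable stop-carrying variants. Motif templates are
planted at recorded positions with a ±10-nt exclusion buffer so that an
incidental nearby mutation cannot merge into a planted group and change
its canonical key — without the buffer, exact motif round-trips would be
impossible by construction rather than by defect. Truth-table effects are
recomputed from the finished variant, so the profiler's effect calls are
comparable even when a codon carries two planted changes.

What the generator does **not** emulate: phylogenetically correlated
variation (members are independent draws, real repositories are
tree-structured), indels, sequencing artifacts, and annotation ambiguity.
A passing round-trip therefore demonstrates that the profiler and miners
are *internally correct* under the stated statistical structure — not
that the pipeline's biological shortlists on real databases are optimal.

# Pipeline orchestration

A cycle runs filter → profile → hotspots/patterns → (protein stages when
annotations or binding sites are configured) → candidate selection,
writes every artifact as TSV/CSV plus a JSON parameter log, and carries
the top `depth` non-excluded candidates forward (clamping with a logged
warning when fewer survive). The per-cycle acquisition of new database
hits is replaced by an injectable sequence source; the bundled source
draws fresh synthetic variants, so the control flow of a live ×250
expansion is preserved without any network dependency. Two runs with the
same inputs and seed are byte-identical, which the acceptance-level test
asserts with file checksums.

# Problem sizes used by the test suite

The suite profiles the full-scale reference (1,281 nt) where the claim
depends on it — 50 seeded repositories of 20 variants for truth-table
round-trips, and a 4-cycle pass at depths 25/25/40/25 with a 60-per-cycle
synthetic source for the determinism check — and drops to 100–300-nt toy
references for oracle-equivalence properties, where exhaustive
enumeration (all global alignments of length-≤6 strings; dictionary
hotspot counts; brute-force minimum distances) is the point. These sizes
were chosen to keep each property readable and quick while exercising the
same code paths as the full scale.

# Known limitations

* Docking, cavity detection, structure prediction and hydrogen-bond
  network analysis are consumed as configuration, never recomputed; the
  binding-site fixture is a transcription and inherits any reading error
  of the published residue lists.
* The κ normalizer is a block-family approximation (see above); values
  for sequences with fewer than ~5 charged residues carry little
  information even when not clamped.
* Frameshifted members are profiled but their codon effects are
  `"ambiguous"` by design; a repository dominated by indels needs a
  different tool.
* The published reference-protein κ (0.17 for the 426-residue reference
  enzyme) requires the actual deposited sequence, which this package does
  not bundle; `chargePattern()` reproduces the arithmetic on any supplied
  sequence.
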