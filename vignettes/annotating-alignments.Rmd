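---
title: "Annotating sequence–structure alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating sequence-structure alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science inside `structaln`: the models and
conventions behind each annotation, the tunable parameters and why
their defaults are what they are, what the synthetic-data generators do
and do not emulate, and the numerical choices that make the pipeline
deterministic.

## The problem

A sequence–structure alignment mixes rows with experimentally known
3-D coordinates and rows that are sequence only.  Such alignments drive
comparative modelling, evolutionary analysis and construct design, and
their quality is judged structurally: a good alignment places buried
positions under buried positions, preserves the hydrogen-bonded core,
and superposes equivalent Cα atoms closely.  `structaln` computes
those diagnostics per residue and per column and typesets them onto the
alignment.

## Input contracts

FASTA and PIR/ALI are accepted.  PIR role tags map `structure`,
`structureX`, `structureN` → structure, `structureM` → model, and
`sequence` → sequence; the simplified dialect with only the first
description field populated is accepted, and the writer emits it.
Both `-` and `.` are read as gaps; `-` is written.  The ungapped
alignment sequence of every structure row must be *identical* to the
sequence observed in the coordinate (ATOM) records — not the SEQRES
sequence, which may include unresolved residues; a mismatch is reported
with the first differing position and both letters, since this is the
most common user error.  Structures pair with rows by file base name
equal to the sequence id; there is no fuzzy matching.  PDB parsing
(through `bio3d`) keeps the first alternate location, treats MSE as
methionine, maps other nonstandard polymer residues to `X` (which then
matches any structure residue), keeps other polymer chains for
interface analysis and all non-water HETATM groups as ligands.  The
default cap of 25 sequences is a validation parameter, not a constant.

## Per-residue features

**Secondary structure.**  Assignment follows the classic backbone
hydrogen-bond energy treatment.  Amide hydrogens are rebuilt 1.0 Å from
N along the preceding carbonyl C=O direction (none on proline or after
a chain break); the bond energy between donor *i* and acceptor *j* is
`E = 0.084·332·(1/d_ON + 1/d_CH − 1/d_OH − 1/d_CN)` kcal/mol, a bond
when `E < −0.5`.  Two consecutive i→i+4 bonds make α-helix (`H`,
minimum run 4), two consecutive i→i+3 bonds 3₁₀-helix (`G`, minimum 3,
reported separately from `H`), and ladders of parallel/antiparallel
bridge patterns make strand (`E`, minimum 2, bridges require sequence
separation > 2).  Overlaps resolve H, then E, then G.  Chains shorter
than three residues are coil.

**Accessibility and burial.**  Shrake–Rupley sphere sampling with a
1.4 Å probe and, by default, 480 points per atom; the point set is a
golden-section spiral, so areas are reproducible bit for bit.  The
chain is analysed in isolation — partner chains and ligands do not
occlude, so burial means burial in the chain's own fold.  Relative
accessibility divides by the residue's theoretical maximum in an
extended Gly-X-Gly tripeptide (the table is a single config block and
can be swapped for an empirical one).  A residue is buried when its
relative accessibility is strictly below 7%.

**Residue depth.**  The retained (solvent-exposed) sample points form a
discrete model of the solvent-accessible surface; an atom's depth is
its nearest distance to that point set and a residue's depth is the
mean over heavy atoms.  This sampled-surface approximation replaces a
full Euclidean distance transform: it converges to the same quantity
with sampling density, is deterministic, and reuses work already done
for accessibility.  A fully exposed atom has depth ≈ r_vdW + probe, so
depths are always ≥ 1.4 Å.  The related pocket-accessibility metric
(minimum inaccessible probe radius) is deliberately not implemented;
the grey background channel in the rendering always carries depth.

**Torsions and hydrogen bonds.**  φ/ψ are IUPAC torsions in
(−180°, 180°], undefined at termini, across breaks (C–N ≥ 2.5 Å) and
where backbone atoms are missing.  Sidechain→mainchain bonds use a
fixed table of polar sidechain N/O atoms, a 3.5 Å donor–acceptor
cutoff, and an N–H⋯acceptor angle > 90° when the amide hydrogen can be
rebuilt; these are stated conventions, chosen once.

**Contacts and interfaces.**  Two residues are in contact when any
heavy-atom pair is within 6.0 Å (sequence neighbours included; hydrogens
never considered).  A cell list of side 6 Å accelerates the search and
is tested to be identical to the all-pairs scan.  Interface membership
uses a 5 Å minimum-distance test against each other polymer chain and
each non-water hetero group, computed on the coordinates as given (no
assembly expansion); when several partners qualify, the nearest one is
reported so exactly one bar can be drawn.

## Per-column features

**Entropy.**  With `f_a` the frequency of amino acid *a* at the column
and `f_gap` the gap frequency (both over all N rows), the conservation
score is `S = −Σ_a f_a log_n f_a + f_gap`, `n = min(20, N)`,
`0·log 0 = 0`.  The negative sign on the sum is required for the stated
bounds — 0 for a fully conserved gap-free column, 1 when all residues
differ — and the gap term enters linearly, so gaps in a conserved
column raise the score.  `X` counts in the denominator but joins
neither the 20-term sum nor the gap term.  A single-sequence alignment
has no defined log base; its entropy is 0 by convention, and the result
is clamped to [0, 1] against floating-point drift.  Symbols: `*` only
at exactly S = 0, then digits over half-open intervals (0 for
0 < S ≤ 0.1, 1 for 0.1 < S ≤ 0.2, …).

**Consensus.**  Only structure/model rows with assigned secondary
structure participate.  The denominator counts all participating rows,
so a gap dilutes the consensus — a conservative choice where the
convention was open.  At ≥ 70% the column shows `a`, `b` or `3`; no
tie-break is needed since only one class can reach 70%.

**Superposition and RMSD.**  Structures are superposed over the
columns where *every* participating structure has a Cα (at least 3
required).  The fit is an iterative inverse-variance-weighted
generalized Procrustes: an initial unit-weight Kabsch fit onto the
first structure, then repeated weighted refits onto the running mean
with per-column weights `1/(variance + ε)`, `ε = 10⁻⁶ Å²`, until the
mean structure moves < 10⁻⁶ Å RMS or 100 iterations.  The weighting
serves the same purpose as maximum-likelihood superposition: flexible
regions are downweighted instead of excluded by an arbitrary distance
threshold, so a rigid core is fitted tightly even when a domain swings
away (the hinge fixture demonstrates a core fitted to ~10⁻⁶ Å where an
unweighted fit compromises at several Å).  Column RMSD is the root
mean square over all unordered pairs of superposed Cα atoms at the
column — for two structures this reduces to the plain pairwise
distance, which is why the all-pairs form was chosen over deviation
from the mean.  It is undefined (blank) where fewer than two
structures have a residue.  Bins [0,2), [2,4), [4,6), [6,8), [8,∞) Å
map to glyphs `_ ▂ ▄ ▆ █`.

**Sequence identity.**  PID between the first non-structure row and
each structure counts identical pairs over columns where both rows
have a residue; with no shared columns it is reported as 0 with an
`undefined` flag.

## Prediction tracks

Secondary-structure and disorder predictions are *inputs*: producing
them requires sequence databases and external predictors, so the
package defines a plain-TSV dialect (`index residue helix strand coil
disorder`) next to the classic .ss2 table (fixed coil/helix/strand
column order) and cross-checks the residue column against the
alignment row.  Only the first sequence-role row is eligible, plus
every model-tagged row.  Rendering thresholds: the dominant of helix
and strand renders strong at confidence ≥ 0.7 and weak in [0.3, 0.7);
disorder (0–9 scale, 0–1 dialects mapped by `floor(10·conf)` capped at
9) renders at ≥ 8.  An exact helix/strand tie renders nothing.

## Document and rendering

All tracks aggregate into one XML document (format version 1.0, XSD in
`inst/schema/`): alignment rows with per-residue feature attributes,
the column track, superposition transforms/weights, the PID table, and
a provenance block echoing every parameter.  Floats serialize at 6
significant digits and the round-trip is lossless at that precision;
documents are validated against the schema and range checks on read.
Structure coordinates are deliberately not part of the document — they
travel as the superposed-PDB archive instead.

HTML rendering is a pure function of the document: case encodes burial
(uppercase = buried), colour encodes secondary structure on structure
rows (α red, 3₁₀ maroon, β blue) and the Taylor physicochemical wheel
on sequence rows, italic marks positive φ, bold a sidechain→amide
bond, underline a sidechain→carbonyl bond, an 8-level grey background
encodes depth normalized to the job's min–max (lightest = shallowest),
and coloured top/bottom bars mark chain/ligand partners with a
deterministic palette (sorted partner names).  Blocks wrap at 60
columns by default.  The interactive-lite mode attaches a parseable
`data-feat` attribute to every residue span — a static stand-in for
hover details; print mode drops metadata and ink-heavy backgrounds.
The five RMSD glyphs are Unicode block elements approximating
increasing-height bars.  The superposed structures are bundled as a
gzipped tar, written by base R so no external archiver is needed.

## Synthetic data: what it emulates, what it does not

The generators build poly-Ala backbones (N, CA, C, O, CB) from
standard bond lengths and angles (N–CA 1.458, CA–C 1.525, C–N 1.329,
C=O 1.231 Å; ω = 180°) at requested torsions: α-helix (−57, −47),
3₁₀ (−49, −26), extended strand (−139, 135).  The two-strand
antiparallel sheet is assembled by a deterministic registry search —
the second strand is the first rotated 180° through its centroid, and
placements are scored by the count of inter-strand hydrogen bonds with
sound geometry (N⋯O 2.5–3.3 Å, N–H⋯O > 130°), ties broken by grid
order.  Toy complexes place a partner chain or a single-atom ligand at
an exact minimum distance (approached from below at 10⁻¹² Å, so a
cutoff equal to the nominal gap still registers).  Toy alignments draw
columns from conservation profiles (conserved / all-different /
random / mixed-with-gaps) with known ground-truth entropies, and can
attach one noisy ideal helix per row plus a rigid hinge displacement
of the second half — giving superposition tests an analytically known
answer.

What the fixtures do *not* emulate: real sidechains beyond Cβ, loop
and turn geometry, crystallographic noise models, missing density,
alternate conformations in anger, or realistic amino-acid composition.
Passing tests therefore demonstrate correctness of the geometry,
statistics and formats on idealized inputs, not robustness to every
pathology of deposited PDB files.

All generators are pure functions of their arguments and an explicit
seed (the global RNG stream is saved and restored), and every geometric
computation downstream is deterministic, so repeated runs are
byte-identical.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `burial_threshold` | 7 | % rel. SASA | burial, strict `<` |
| `probe_radius` | 1.4 | Å | solvent probe |
| `n_sphere_points` | 480 | – | SASA/depth sampling density |
| `hbond_cutoff` | 3.5 | Å | sidechain–mainchain donor–acceptor |
| `contact_cutoff` | 6.0 | Å | intra-chain contacts |
| `interface_cutoff` | 5.0 | Å | chain/ligand interfaces |
| `consensus_threshold` | 0.70 | fraction | SS consensus |
| `pred_strong` / `pred_weak` | 0.7 / 0.3 | confidence | prediction rendering |
| `disorder_threshold` | 8 | 0–9 | disorder rendering |
| `rmsd_bin_edges` | 2,4,6,8 | Å | RMSD glyph bins |
| `max_sequences` | 25 | – | validation limit |
| `wrap_width` | 60 | columns | HTML blocks |

The thresholds are the published conventions of the annotation style
this package implements; sampling density and wrap width balance
precision against output size and were chosen once.

## Numerical choices and degenerate inputs

Sphere sampling is deterministic (no RNG in any geometric code path);
480 points give ≈ 1% area precision, and the tests that compare
against closed-form two-sphere areas use 960.  The superposition
variance floor ε = 10⁻⁶ Å² caps weights for perfectly conserved
columns; convergence at 10⁻⁶ Å RMS mean-structure shift typically
takes 10–20 iterations.  Contact/interface boundaries are inclusive
(`≤ cutoff`); burial is exclusive (`< threshold`); entropy symbol
intervals are half-open with `*` reserved for exactly 0.  Degenerate
inputs are defined, not errors, wherever a convention exists: chains
of one or two residues are all-coil with undefined torsions, a single
structure skips superposition and leaves the RMSD row out, a single
sequence has entropy 0, an unknown residue type gets undefined relative
accessibility and is never called buried.  Hard errors are reserved
for contract violations: ragged alignments, all-gap columns, unknown
role tags, missing chains, sequence/structure mismatches, and
superposition with fewer than three shared columns.

Test and acceptance problem sizes — 12–20-residue chains, 2–4
sequences, 8–20 columns — are the package's chosen desk scale: large
enough to exercise every code path (helix interiors, strand ladders,
hinge cores, wrapped rendering) while keeping the whole suite
interactive.

## Known limitations

* Burial and depth are computed on the isolated chain; a residue at a
  biological interface can be "exposed" here yet buried in the
  assembly.
* The secondary-structure assignment covers H/G/E/C only (no π-helix,
  bends or turns) and, like any H-bond-energy method, is sensitive to
  missing backbone oxygens.
* The superposition is a weighted least-squares approximation of
  maximum-likelihood fitting: it shares the downweighting rationale
  but not the full covariance model.
* Contacts and interfaces use the deposited coordinates as given;
  crystal packing is not distinguished from biological contact.
* The XML schema is this package's own; it aims at the same content as
  other alignment-annotation containers but not byte compatibility.
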