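---
title: "Methods: split-site screening and rearrangement calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-site screening and rearrangement calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and parameter choices
behind the two workflows, in the spirit of a methods section: what is
computed, under which assumptions, and where the defaults come from.

## Structure models and confidence

A `structure_model` is an ordered atom table plus a chain-level entity map
(protein / DNA / ion / ligand), assigned from residue names: the twenty
amino-acid codes are protein, DA/DT/DG/DC are DNA, MG is an ion, FAD a
ligand, and anything unrecognised becomes a ligand with a warning. Per-atom
confidence is read from the B-factor column, where structure-prediction
servers write pLDDT (0–100). PDB reading and writing and mmCIF reading go
through `bio3d`; mmCIF support is read-only and limited to the `atom_site`
loop (auth identifiers preferred), which is all a predicted model contains.
Alternate locations other than blank/'A' are dropped. Hydrogens are kept in
the model but excluded from SASA and hydrogen-bond geometry by default,
since predicted models are hydrogen-free.

**Mean pLDDT** is averaged per residue first (unweighted over the residue's
atoms) and then over residues. Servers emit one value per residue copied to
every atom, so the two conventions coincide on server output; on mixed
hand-built fixtures they differ, and the per-residue convention is the one
documented here. Whether published per-model averages were per-residue or
per-atom is generally not stated; this choice is therefore a documented
convention rather than a reproduction guarantee.

**Superposition** is the standard Kabsch least-squares rigid-body fit via
SVD, with the reflection branch disabled (determinant forced to +1) and an
error on rank-deficient (collinear) inputs, where the rotation about the
common axis would be undetermined. The reported RMSD is post-fit.

## SASA and buried interface area

The solvent-accessible surface area engine is a Shrake–Rupley
construction: each atom's sphere of radius (r_vdW + r_probe) carries a
fixed golden-spiral lattice of test points; points inside any neighbour's
expanded sphere are occluded, and the atom's SASA is the accessible
fraction of the full sphere area. Defaults: probe 1.4 Å (water), 960
points per atom, Bondi-style radii C 1.70, N 1.55, O 1.52, P 1.80, S
1.80, Mg 1.73, H 1.20 Å, with 1.70 Å as the warned fallback for unknown
elements. The lattice has a fixed ordering, so results are bit-reproducible
for a given point count; because the lattice is fixed in space, rigid-body
invariance holds to point-sampling resolution (empirically well under 0.5 %
at 960 points, which is also the observed doubling-convergence bound).

Buried (interface) area between two chain groups is
`SASA(A) + SASA(B) − SASA(A∪B)`, each part recomputed in isolation. The
non-negative "buried area" convention is used throughout: larger values
mean larger interfaces. A published ΔSASA defined verbally as "complex
minus parts" would carry the opposite sign; adopting burial ≥ 0 keeps
"larger interface, more stabilising" readable and makes an inverse
burial–ΔG correlation the expected sign. Published absolute Ų values from
other programs are not reproduced exactly, since their radii sets and point
densities are not specified; all within-package comparisons are
self-consistent.

## Hydrogen bonds, ion coordination, cleavage

Hydrogen bonds use a heavy-atom donor–acceptor distance criterion
(≤ 3.5 Å), with no angle term — the appropriate level for hydrogen-free
predicted models. Donor/acceptor tables: protein backbone N donates and
backbone O accepts; side-chain donors are Lys NZ, Arg NE/NH1/NH2, Ser OG,
Thr OG1, Tyr OH, Trp NE1, His ND1/NE2, Asn ND2, Gln NE2; side-chain
acceptors the carboxylate/amide/hydroxyl O and His N; DNA bases
donate/accept at their Watson–Crick edge atoms and the backbone oxygens
accept. The default `inter_entity` mode reports protein↔DNA pairs only,
matching the usual interface question; `all` keeps every pair across or
within entities except same-residue pairs.

Mg²⁺ coordination lists N/O atoms within 3.0 Å of each ion — generous
relative to the ~2.1 Å ideal Mg–O distance, deliberately absorbing
predicted-model error.

Cleavage inference reads the cut off the geometry: each catalytic ion is
assigned to its nearest backbone phosphorus within 6.0 Å (ties broken by
lower residue number); the scissile bond is the phosphodiester bond 5′ of
that phosphate's nucleotide, with bonds indexed 0-based so bond *i* lies
5′ of nucleotide *i* on its strand. Base pairing between the two DNA
chains is established from complementarity plus spatial proximity of base
reference atoms — never from residue numbering — and must be antiparallel
and monotonic, otherwise the duplex is rejected. Both cuts are mapped to
the top strand's axis; the signed offset gives overhang length, the
top-strand sequence of the single-stranded region, and the end type
(positive offset 5′ overhang, negative 3′, zero blunt). An ion with no
phosphorus in range is skipped with a warning; if a strand ends up without
a cut the call is flagged incomplete and no overhang is reported.

## Split-site screening

Candidates are enumerated symmetrically around the original split
(default ± 7, i.e. 15 positions) — the window is configurable, and 15 is
also the pair count at which a Pearson r of −0.53 has a two-sided
t-transform p of 0.042, the worked example used in the tests. Pearson
correlation is delegated to `stats::cor.test`, whose p-value is exactly
the t transform `t = r√((n−2)/(1−r²))` on n−2 degrees of freedom;
`pearson_p(r, n)` exposes that transform directly. Selection uses strict
Pareto dominance over the baseline (burial strictly larger and ΔG strictly
lower), ordered by descending burial with ties broken by ascending ΔG and
then ascending split position; no randomness anywhere, and an empty
dominated set is reported as "no improvement" rather than forcing a
winner. Whether a published selection used strict dominance or visual
inspection of a scatter plot is usually unknowable; strict dominance is
the reproducible choice.

## Rearrangement calling

All segmentation thresholds are this package's operational choices — the
qualitative rules (LOH from depth and allele frequency; telomere-reaching
tracts are BIR, interstitial tracts SGC; repeats-flanked junctions NAHR,
the rest NMTL) are standard, but published analyses rarely print their
numeric cutoffs. Defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| `min_depth` | 10 | below ~10 reads an allele fraction is too noisy to band |
| `het_band` | 0.25–0.75 | ±3 binomial SD around 0.5 at depth ~30 |
| `hom_band` | 0.10 | tolerates stray mismapped reads at hom sites |
| `min_run` | 5 markers | rejects isolated genotyping errors |
| `max_discordant_frac` | 0.10 | tolerates sparse het/nocall inside a tract |
| `end_margin` | 20 kb | subtelomeric marker deserts in yeast-sized genomes |
| `gain_ratio` / `loss_ratio` | 1.25 / 0.75 | midpoints toward the 1.5 / 0.5 dosage of trisomy/monosomy in a diploid |

LOH segmentation chains concordant homozygous markers greedily left to
right; an opposite-haplotype marker always terminates a run, het/nocall
markers are tolerated up to the discordant fraction, and segments span
first to last concordant marker — so reported boundaries are
marker-resolution, not base-resolution. A segment is BIR when its span
comes within `end_margin` of either chromosome end or contains the first
or last marker of the chromosome (reaching the start of a chromosome is
also "a chromosome end"). Segments of the two haplotypes can never
overlap, which the tests assert by re-scanning.

Aneuploidy normalises each chromosome's median marker depth by the
genome-wide median. With few chromosomes a gained chromosome inflates the
genome median, biasing ratios toward 1 (a 4-chromosome trisomy measures
~1.4 rather than 1.5); the 1.25/0.75 thresholds absorb this, but callers
on very small genomes should expect attenuated ratios. Single-chromosome
input is rejected since the normaliser would be the signal itself.

Breakpoint motif checks search for the motif or its reverse complement
overlapping the junction point within ± one motif length; the flank
convention places the junction at the string midpoint (cut between
characters 20 and 21 of a 40-mer). GATC is its own reverse complement, so
the rc path only matters for non-palindromic motifs — it is included for
generality.

Control subtraction removes segment events at ≥ 50 % reciprocal overlap
with any control segment and junction events whose breakpoints both fall
within 1 kb of a control junction's. The per-isolate report sums LOH tract
lengths over merged SGC+BIR intervals and CNV tract lengths over merged
dosage-altered intervals (aneuploidy, plus any pre-typed segment events
such as large deletions; junction-only events carry no length). An isolate
whose merged LOH covers ≥ 95 % of the marker-bearing genome is flagged
excluded — the operational proxy for haploidization, which published
analyses exclude qualitatively as "complete loss of heterozygosity".

## Statistics

The two-sample comparison is the two-sided Mann–Whitney–Wilcoxon test via
`stats::wilcox.test`: exact by enumeration when the smaller sample has at
most 8 observations and there are no ties, otherwise the normal
approximation with tie and continuity corrections. The suite checks the
2×2 enumeration case (p = 1/3), exact-vs-approximate agreement within 0.02
at 8×8, and type-I calibration (0.05 ± 0.02 over 2,000 null pairs at a
fixed seed). Box statistics use linearly interpolated quartiles
(`quantile` type 7) with whiskers at the most extreme points within
1.5×IQR — the common R plotting convention (note `boxplot.stats` uses
Tukey hinges instead, which differ on small samples). Fragmentation
arithmetic sums instrument fragment mass inside a closed 200–48,500 bp
window and normalises light by dark; percent changes are reported to one
decimal. Fold changes between group means are computed from unrounded
means.

## Synthetic data: what it emulates, and what it does not

The genome generator emulates a two-parent fusion diploid: haplotype 1 is
uniform random sequence, haplotype 2 differs at independent positions at
the divergence rate (default 0.007, i.e. 0.7 % SNPs), and those positions
are the markers. Each 10 kb window is resampled until it contains the
recognition motif, so junction snapping cannot fail on small test genomes
(a GATC occurs ~39 times per 10 kb at random expectation, so resampling
is almost never triggered). Depth is Poisson with mean coverage × dosage
(default 30×), split binomially between alleles at the expected haplotype
fraction (0.5 het; 0 or 1 inside LOH; 1/3 or 2/3 under trisomy); a
negative-binomial overdispersion knob exists but is off by default.
Implanted events are validated (LOH intervals must not conflict, NMTL
breakpoints snap to the nearest motif, NAHR breakpoints must sit in the
supplied repeat intervals) and returned as ground truth for recovery
scoring.

Real data differ in ways the generator deliberately ignores: SNP spacing
in real hybrid genomes is non-uniform (marker deserts around centromeres
and introgressions), mapping artefacts produce locally correlated
genotyping errors rather than independent ones, real junction flanks are
chimeric across the breakpoint, and sequencing error is absent entirely.
Passing the recovery suite therefore demonstrates the correctness of the
calling logic under its stated evidence model, not robustness to
alignment artefacts — the caller starts from marker tables by design, and
read-level processing is out of scope.

Test problem sizes are chosen to exercise every code path at desk scale:
recovery runs use twenty replicate 4-chromosome × 120 kb genomes (~3,400
markers each) with one implanted event of each class, and the
marker-density checks use a single 1 Mb chromosome, where three binomial
standard deviations around the expected 7,000 markers is ±250.

## Known limitations

- SASA is O(n²) in atoms per call and pure R; it is sized for per-variant
  screening models and fixtures, not for trajectory-scale workloads.
- Cleavage inference assumes one duplex and one cut per strand; nicking
  enzymes and multi-duplex assemblies are rejected or flagged incomplete.
- The LOH caller reports marker-bounded segments; true tract boundaries
  between markers are unknowable from marker evidence alone.
- ΔG values are consumed, never computed; the screening result is only as
  good as the supplied stability table.
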