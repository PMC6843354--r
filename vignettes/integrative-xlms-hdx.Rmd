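---
title: "Models and methods behind xlhdx"
author: "xlhdx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xlhdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlhdx)
```

`xlhdx` analyses the three data streams of an integrative structural-MS
study of a transcription-factor DBD bound to its DNA response element:
deconvoluted intact and bottom-up neutral-mass lists from cross-linking
reactions, isotope-doublet intensities for quantitative cross-linking, and
HDX centroid time courses. This vignette describes the models, the
parameters that matter, and the choices made where the design was open.

## Mass model

Every mass is a neutral monoisotopic mass assembled from elemental
compositions (`element_masses()`): peptides as residue compositions plus
one water, DNA as nucleoside compositions with HPO~3~-for-water
phosphodiester linkages and explicit 5′/3′ terminus chemistry (default
5′-OH/3′-OH, matching synthetic oligonucleotides; peptides default to free
amine/free acid). Charge states never appear: the inputs are
charge-collapsed deconvoluted masses.

Cross-linker bridges are the net atoms added on double aminolysis:
C~5~H~4~O~2~ for DSG (+96.0211 Da) and C~8~H~10~O~2~ for DSS
(+138.0681 Da); the d4 forms substitute four deuteriums, giving the
4.0251 Da doublet spacing; a mono-link adds the hydrolyzed bridge
(+H~2~O). Transplatin chemistry adds Pt(NH~3~)~2~ (+229.0179 Da,
bifunctional bridge) or Pt(NH~3~)~2~Cl (+263.9867 Da, monofunctional
"dangling" adduct).

Two choices here are interpretations rather than measurements:

* **Pt reference isotope.** Platinum's isotope envelope is broad, so the
  monoisotopic reference must be declared. The default is ¹⁹⁵Pt
  (194.964792 Da, the most abundant isotope, which deconvolution software
  uses to anchor the reported peak); ¹⁹⁴Pt is available via
  `pt_adduct(pt_isotope = "194Pt")`.
* **No proton displacement.** Pt coordination is assumed to add the full
  adduct formula with no hydrogen loss from the target residues. Reported
  Pt–protein chemistry does not settle whether coordination displaces a
  proton on protein ligands; the no-loss convention is a documented
  default, not a derived fact.

## Digestion and annealing

Trypsin cleaves after K/R unless the next residue is proline (the standard
specificity; the rule is on by default), generating peptides for 0..k
missed cleavages with 1-based inclusive positions in construct numbering.
Bal-31 is biochemically an exonuclease, but the fragment species actually
present after partial digestion are not enumerable in advance, so the
default fragment model is *all contiguous substrings above a minimum
length* — a superset that cannot cost a true conjugate during library
matching — with an end-truncation-only mode for the strict exonuclease
picture. Annealing maximizes Watson–Crick pairs over all ungapped offsets
of one strand against the reverse complement of the other.

Construct numbering is deliberately user-controlled (`start_pos`,
`offset` arguments): recombinant constructs carry vector-derived leaders,
and structure files use their own numbering, so a single internal
numbering with explicit offsets is safer than guessing.

## Cross-link search

The library enumerates every type-valid candidate whose components carry
the required reactive classes: K/S side chains plus the protein N-terminal
amine for NHS-ester linkers, and C/M/H/T versus guanine for transplatin.
Matching is **mass-only**: Pt-bridged hetero-conjugates dissociate around
the Pt atom under gas-phase activation and yield no backbone fragments, so
no MS/MS scoring tier exists to break ties. Consequently ambiguity is
preserved, never resolved by guessing: every candidate within the ppm
tolerance is reported, ranked by absolute ppm error, then fewer
components, then lexicographic component order (a deterministic, reportable
tie-break). Pt identifications are flagged *composition-only* — the
conjugated components are known, the bridged residues are not. The default
tolerance is 5 ppm: calibrated FTICR data is good to about 1 ppm, and the
margin absorbs deconvolution error. Intra-peptide loop-links are generated
for completeness and flagged by type.

The *constant unit* path treats one designated oligonucleotide fragment
plus a bifunctional Pt equivalent as a fixed mass appended to every
reactive peptide — the practical way to search peptide–DNA conjugates when
the oligonucleotide moiety has been trimmed to a known species.

## Quantitative cross-linking

Doublet partitioning is exact intensity arithmetic,
`%light = I_L/(I_L + I_H) × 100`, on deconvoluted peak intensities as-is:
no isotope-envelope overlap correction is attempted at +4 Da, which is a
documented limitation rather than an oversight. Two routes find the
doublets. `pair_doublets()` is a blind survey: greedy on descending
light-peak intensity with single-use peaks — deterministic, and the way a
human picks doublets in a spectrum viewer. `quantify_conjugates()` is the
targeted route used once identifications exist: it looks up each
conjugate's light and heavy masses directly, and is therefore immune to
accidental 4-Da spacings among unrelated peaks. Replicates aggregate as
mean ± sample sd; a single replicate reports sd 0 with an explicit flag.
The differential report labels a conjugate `inhibited` or `enhanced` when
`|%free − %bound|` exceeds a threshold defaulting to 10 percentage points
— the underlying reports are qualitative about direction, so the threshold
is a configurable reporting convention, not an inference procedure.

## HDX model

Peptide-level relative deuteration is `DR = (m_t − m_0)/N_ex` against a
time-0 undeuterated reference, clamped to [0, 1] with clamp counting.
`N_ex = L − 1 − #Pro(2..L)`: the N-terminal amide back-exchanges too fast
to observe and proline has none. The alternative convention that also
discounts the second residue is available (`rule = "skip_first_two"`). No
back-exchange normalization is applied by default — quench conditions are
assumed to minimize it, and only relative comparisons between states are
drawn; a fully-deuterated-control mode can be emulated by supplying
normalized centroids.

Residue-level consolidation works in deuteron units on the *covered
residue set* of each peptide (positions start+1..end minus prolines).
Peptide boundaries partition covered residues into atomic segments;
peptides are processed shortest first, and each peptide's uptake not yet
explained by assigned segments is attributed to its unassigned segments in
proportion to their amide counts. This is deterministic and auditable; a
minimum-norm least-squares mode solves the same segment system globally,
and the two agree on fully determined systems. Negative remainders beyond
1e-6 Da are clamped to zero and counted; per-peptide residuals are
reported so inconsistent overlap systems are visible rather than silently
smoothed. Resolution is inherently segment-level: residues inside an
unresolved segment share its DR, and protection windows are recovered
exactly only where peptide boundaries resolve them.

Differential profiles are `ΔDR = DR_free − DR_complex` on a strictly
matched residue × timepoint grid (missing cells are errors, never
interpolated). Significance uses `|ΔDR| > k·sd_diff` with k = 2 and
`sd_diff` combining the replicate sds of both states; the original
reports draw shaded significance bands without stating a criterion, so the
k·sd rule is a documented substitute. Differences below 1e-9 are zeroed —
consolidation round-off must not become "significant" when replicate sd is
exactly zero. Time courses are classified (`rising-saturating`,
`rise-then-fall`, `flat`, `other`) from the sign pattern of successive
differences inside a noise band, and residues with significant positive
ΔDR at any timepoint export as the docking-active list.

## Distance restraints

DSG and DSS identifications become restraints with spans 20.5 ± 3.0 Å and
24.2 ± 3.0 Å between bridged residues — spans that already fold in the
spacer arm and side-chain reach, which is why measurement uses fixed,
documented atoms: Cα for protein residues and guanine N7 for DNA.
Class-ambiguous sites expand into one ambiguous group per identification,
satisfied if any member is; Pt identifications expand over reactive
residues × reactive bases. The Pt bridging span (5.0 ± 2.0 Å between
donor heteroatoms, from trans coordination geometry plus side-chain slack)
is a package default with no experimental calibration behind it, and is
flagged as such. Unresolvable endpoints are reported not-evaluable, never
dropped. Export formats are a TSV (byte-stable, round-trippable),
simulated-annealing `assign` records, and docking-style ambiguous-group
blocks.

## What the synthetic generator emulates — and what it does not

`scenario_config()` encodes the study conditions: a ~130-residue construct
numbered from residue 74, the printed 13-mer duplex strands, 1 ppm mass
noise, 200 decoys kept ≥ 50 ppm from every library mass, triplicates, the
eight-point exchange schedule 0.33–300 min, and a protection window at
residues 103–130 raised 100-fold in the bound state. Folds are
self-avoiding 3.8 Å Cα chains; the duplex is an ideal B-form helix
(3.4 Å rise, 36° twist) with pseudo-atoms sufficient for restraint
measurement. Exchange kinetics are single-exponential per residue,
`u_i(t) = 1 − exp(−k_int·t/P_i)`, with one global intrinsic rate constant:
sequence-dependent intrinsic-rate tables would obscure the
parameter-recovery tests, and the analysis itself performs no
intrinsic-rate correction. Intensity noise is multiplicative log-normal
(cv 5%), matching MS intensity error character.

The generator does **not** emulate: isotope envelopes or charge states,
chromatography and co-elution, EX1 bimodality, back-exchange, non-specific
cross-linking, or real protein topology. Passing tests therefore
demonstrate correctness of the computational chain under controlled truth
— recall on planted conjugates, mixing-fraction recovery, consolidation
exactness, restraint satisfaction on the generating fold — not robustness
to every pathology of real spectra.

Test and scenario sizes (134-residue folds, 20 planted cross-links,
30–100 replicate draws for statistical checks) were chosen so the full
suite exercises every stage, including end-to-end closure, while staying
small enough to run routinely.

## Known limitations

* Mass-only identification cannot separate isobaric candidates; ambiguity
  is reported, not resolved.
* Intensity partitioning ignores +4 Da envelope overlap and detector
  saturation.
* Segment-level HDX resolution depends entirely on the peptide pool;
  sparse overlap degrades to peptide-level resolution.
* The Pt restraint span is a geometric default; treat Pt-derived
  restraints as component-level evidence.
* Bal-31 substring enumeration over-generates candidates; with very large
  oligonucleotide pools, prefer the constant-unit path.
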