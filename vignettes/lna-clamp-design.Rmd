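---
title: "Designing LNA primers and host-blocking clamps for fungal ITS amplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing LNA primers and host-blocking clamps for fungal ITS amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnaclamp)
```

## The problem

Amplicon surveys of plant-associated fungi target the internal transcribed
spacer (ITS) region between the rRNA genes. The primers that amplify it
anneal in the flanking small- and large-subunit rRNA genes, which are nearly
homologous between fungi and their host plants, so DNA extracted from roots
or tubers yields mostly host amplicons and the fungal community is
underestimated. `lnaclamp` implements a two-sided countermeasure:

* **Forward side** — a degenerate, fungus-selective forward primer whose
  fungus-diagnostic bases are substituted with locked nucleic acid (LNA)
  monomers. LNA's 2'-O,4'-C methylene bridge locks the ribose in the
  3'-endo conformation, raising duplex stability and sharpening mismatch
  discrimination, so the primer binds fungal templates preferentially.
* **Reverse side** — a host-specific, 3'-phosphorylated LNA *clamp*
  oligonucleotide that overlaps the universal reverse primer's 3'-terminal
  annealing positions by one or two bases and extends toward the extension
  side, where plant-diagnostic bases exist. During an extra, hotter
  annealing step of each PCR cycle only the clamp hybridizes; being
  non-extendable, it blocks the reverse primer on host templates while
  fungal templates, mismatched to the clamp, remain amplifiable.

The package covers the full desk workflow: alignment handling, column
profiling, degenerate-consensus and LNA planning, clamp candidate
enumeration and Tm tuning, exact-match cross-reactivity screening, melting
temperature prediction, and emission of the clamped-PCR protocol.

## Melting-temperature model

Duplex formation is modelled with nearest-neighbor thermodynamics:

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + R\,\ln(C_T/4)} - 273.15$$

with $\Delta H^\circ$ and $\Delta S^\circ$ summed over dinucleotide stacks
using the unified DNA parameter set (SantaLucia 1998), duplex-initiation
terms per terminal base pair, a symmetry correction for self-complementary
sequences, and the entropic salt correction
$\Delta S^\circ[\mathrm{Na^+}] = \Delta S^\circ[1\,\mathrm{M}] + 0.368\,(N-1)\ln[\mathrm{Na^+}]$.
Divalent cations enter through the monovalent equivalence
$[\mathrm{Na^+}]_{eq} = [\mathrm{Na^+}] + 120\sqrt{[\mathrm{Mg^{2+}}]}$ (mM).

Each LNA base contributes an increment $(\Delta\Delta H, \Delta\Delta S)$ to
every stack it participates in: two stacks for an internal substitution, one
at a terminus, and a stack flanked by two LNA bases receives both
contributions. The shipped increment table
(`inst/extdata/lna_increments_calibrated.tsv`) is the package's **own
calibrated set**, not the published single-substitution parameters: one
$(\Delta\Delta H, \Delta\Delta S)$ pair per LNA base identity, fitted once
against the printed melting temperatures of the three reference clamps
(68/72/69 degC) and the degenerate LNA forward primer range (59-62 degC)
under the default conditions, then frozen. The file is labelled synthetic
accordingly. The fitted set reproduces the qualitative literature ordering —
pyrimidine LNAs stabilize more than purines (single-substitution effects on
a 22-mer: about +1.4 degC for C, +0.6 for T, +0.3 for A, +0.1 for G).

Default conditions are part of that frozen calibration: 240 mM monovalent
cation and 0.8 uM oligonucleotide (the working primer concentration). The
vendor calculator behind the published designs does not disclose its salt
and concentration assumptions, so agreement within +/-2 degC of the printed
anchors, not exact equality, is the verification contract. Degenerate
oligos are expanded (capped at 256 expansions) and the median is reported as
the headline Tm with the min/max always surfaced; LNA on a degenerate
position is rejected because its increment would be undefined.

```{r tm-example}
tm_oligo("CTYGGTCATTTAGAGGAASTAA", lna = c(5, 20, 22))
```

## Forward primer design

`column_profiles()` tallies per-column base frequencies; ambiguous database
bases contribute fractionally and equally to their constituent bases so that
N-rich columns keep their effective depth, and gaps are reported separately.
`degenerate_consensus()` emits, per column, the IUPAC code covering the
modal base plus every base at or above `minor_freq_threshold` (default 0.05:
the source designs added degeneracies for variants present "at a certain
percentage" without quantifying, and 5% is this package's documented
choice). `discriminating_positions()` reports columns where one base
reaches `target_purity` (default 0.95) among fungi while every host group's
modal base differs at `nontarget_purity`; `plan_lna()` converts those
positions to LNA, skipping degenerate positions, preferring positions that
mismatch more host groups and then 3'-proximal ones when `max_lna` (default
4) caps the count. A 3'-terminal LNA is allowed — the reference primer
carries one on its final base.

```{r forward}
aln <- make_forward_fixture(fixture_spec(seed = 1))
design_forward_primer(aln)
```

## Clamp design

Host rows are grouped into identical-sequence types over the design window
(`group_by_identity()`); the study system yields exactly three types (wheat-,
soybean-, and potato-like). For each type, `design_clamp()` enumerates
candidates over overlap (1 then 2 bases) and length (20-25 nt), each the
reverse complement of the host sequence ending at the overlap. Design rules,
where the published account left the procedure open, were fixed as follows:

* **Terminal specificity.** A candidate's 3'-terminal base must be
  host-specific. Every base beyond the last discriminating position is
  complementary to the fungal consensus too, so extending further raises
  fungal affinity without adding host specificity. On the study fixtures
  this makes the candidate length unique per overlap.
* **All specific bases become LNA.** Host-specific, non-overlap positions
  are all converted to LNA (capped at `max_lna_clamp = 6`), mirroring the
  published wording that plant-specific bases *were replaced* with LNA;
  Tm is tuned by overlap and length, not by withholding LNAs. When the cap
  binds, the subset maximizing the minimum pairwise spacing is chosen
  ("equal distribution"), verified in the tests by exhaustive enumeration.
* **Minimal overlap first.** Overlapped bases sit in the reverse primer's
  annealing site, which is conserved between plants and fungi, so they
  dilute specificity; overlap 2 is tried only when no overlap-1 candidate
  reaches the Tm acceptance band. This is what drives the potato-type
  design to a two-base overlap: its overlap-1 candidate melts at ~67.1
  degC, below the band, while wheat and soybean succeed at overlap 1.
* **Tm acceptance.** `tm_target = 70` degC with `tm_tolerance = 2.5`:
  the clamp must outmelt the amplification primers at the clamp-annealing
  step, and the accepted reference designs span 68-72 degC around the
  ~70 degC working point. Among in-band candidates the one closest to
  target wins.

Every clamp is 3'-phosphorylated (non-extendable) and never carries LNA on
an overlap base. `screen_cross_reactivity()` then counts fungal records
whose window is exactly complementary to the clamp over its full length,
in either orientation — the desk equivalent of checking a database for
identical fungal sequences; non-zero counts warn rather than fail, since a
handful of hits is the accepted regime for clamping.

```{r clamps}
rev_aln <- make_reverse_fixture(fixture_spec(seed = 1))
clamps <- design_host_clamps(rev_aln)
clamps$potato
```

## Clamped-PCR protocol

`recommend_clamp_annealing()` places the clamp-annealing step at
`max(primer tm_max + 4, round(clamp Tm))`, never more than 1 degC above the
clamp's own Tm: primers with Tm near 60-62 degC remain functional up to
about 66 degC, while pushing the step past the clamp's Tm would cost
hybridization efficiency and let host templates escape.
`build_clamping_program()` emits the full program — 94 degC/3 min; 40 cycles
of 94 degC/1 min, clamp annealing/1 min, 54 degC/1 min, 72 degC/2 min;
72 degC/10 min — plus the clamp titration series (0-4 uM, extendable to
8 uM for recalcitrant samples) at 0.8 uM primers. `attach_gc_clamp()`
prepends the standard 40-base GC-rich extension for DGGE, and
`nested_pcr_plan()` records the two-stage amplification with the 1e3- to
1e4-fold dilution between rounds.

```{r protocol}
fwd <- design_forward_primer(aln)
build_clamping_program(list(fwd$tm_lna, tm_oligo(ITS4_SEQ)),
                       clamps$wheat$tm)
```

## The synthetic fixtures

`make_forward_fixture()` and `make_reverse_fixture()` generate alignments
with the column structure of the published forward- and reverse-side
figures, at reduced scale (200 rows per fungal phylum by default — the
published alignments used thousands of rows, which add nothing to design
correctness). The forward window carries minor C variants at columns 3 and
19 within Ascomycota at 30% (about 10% overall, comfortably above the 5%
degeneracy threshold), invariant fungus-diagnostic G/T/A at columns 5/20/22,
hosts with A/C/G there, and a 0.5% background substitution rate elsewhere
emulating incidental database variation. The reverse window places host
types as the exact reverse complements of the three reference clamp sites
around the canonical fungal 28S flank; substitution noise is confined to
the flanking columns because that rRNA stretch is essentially invariant
across fungi and the fixture encodes the figure's row-level structure.
All randomness is fixed by the spec seed (`withr::with_seed`), and an
optional planted fungal row identical to the wheat window exercises the
cross-reactivity screen.

What the fixtures do **not** emulate — and hence what passing tests cannot
show — includes real ITS length variation (400-900 bp), chimeras, alignment
error, indel-rich host/fungus divergence, and the composition of any live
sequence database. Quantities that depend on a database snapshot (primer
coverage percentages of real phyla, BLAST hit counts of the clamps) or on
wet-lab behaviour (gel intensities, DGGE patterns, effective clamp
concentrations per sample type) are therefore outside what this package
verifies; the coverage and screening *engines* are tested against
brute-force oracles instead.

## Numerical choices and limitations

* Coordinates are 1-based, inclusive, 5'->3' on the stored strand; gap
  removal is anchored to a designated reference row, never to whole-column
  gap fractions.
* Percent identity rounds half away from zero, consistent with how
  alignment viewers print similarity (204/218 -> 94).
* Degenerate expansion is capped at 256 variants; larger spaces error with
  advice to resolve ambiguities first.
* Candidate/LNA tie-breaks are deterministic: equal-spacing ties prefer the
  larger total spread, then 3'-proximal positions; equal-Tm candidate ties
  prefer the shorter oligo.
* The Tm engine predicts perfect-duplex melting only: no mismatch or
  duplex-hybrid corrections, no hairpin/dimer screening, and a single
  documented divalent-cation formula. The LNA increment table is calibrated
  to this design system; transferring it to unrelated sequence families
  should be done with independent anchors in hand.
* Problem sizes used throughout the documentation and tests (hundreds of
  rows per fixture, 22-45 column windows) are the package's chosen working
  scale; the design outcome is invariant to the row count once column
  frequencies are stable.
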