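---
title: "Designing single-stranded DNA rings with terminal hairpins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing single-stranded DNA rings with terminal hairpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringforge)
```

## The model

A linear single-stranded DNA (l-DNA) is cyclized to a covalently closed
ring by T4 DNA ligase on a splint — a short oligonucleotide complementary
to both termini that juxtaposes them across the nick. The side reaction
that ruins preparative synthesis is intermolecular ligation to linear and
multi-cyclic polymers. A hairpin whose stem begins within a few
nucleotides of a terminus suppresses it: the l-DNA is then mostly folded,
the folded form is a poor ligase substrate, and only the minor *open*
form reacts. Two states are assumed:

$$K = \frac{[\mathrm{folded}]}{[\mathrm{open}]} = e^{-\Delta G/RT},
\qquad [\mathrm{open}] = \frac{c_\mathrm{total}}{1+K},$$

with $\Delta G$ the hairpin folding free energy (negative for a stable
hairpin) and $R = 1.987\times10^{-3}$ kcal/(mol·K). Intramolecular
cyclization is first-order in the open form while polymerization is
second-order, so capping $[\mathrm{open}]$ caps the side reaction
regardless of the total concentration. The package inverts the partition
at a cap of 0.1 μM open form — the working point associated with >85%
ring selectivity — to predict a preparative ceiling
$c_\mathrm{max} = 0.1\,(1+K)$ μM. `K` is propagated unrounded
everywhere; e.g. for $\Delta G = -3.16$ kcal/mol at 25 °C, $K = 207.3$
and $100/(1+K) = 0.480$ μM, whereas rounding $K$ to 210 first would give
0.474 μM.

This is a threshold *classifier*, not a selectivity-versus-concentration
curve: only the 0.1 μM / 85% anchor is modeled. Length of the l-DNA,
splint length and reaction temperature also matter experimentally and
are not modeled; they surface only as the warning for precursors
shorter than 44 nt, below which observed ring selectivity collapses.

## Design rules

Every rotation of the target ring is a valid precursor (all of them
re-ligate to the same ring), so `design_ring()` scans all $n$ scission
sites and evaluates, for each side of each rotation, the hairpin nearest
that terminus:

* **distance** — unpaired nucleotides between terminus and first paired
  stem base; accepted at 1–3 (`d_min`, `d_max`). At 4–5 the hairpin no
  longer shields the ligation site; distance 0 could not be probed
  directly by the underlying position series (sequence changes refold
  the molecule), so it is accepted only under `permissive_distance0`,
  since stems starting at nt 1 still performed well in the stability
  series.
* **stability** — folding $\Delta G \le -3$ kcal/mol, so the folded form
  dominates ~150:1 or better at 25 °C.
* **melting window** — 50 °C ≤ Tm ≤ 80 °C. The floor matches the
  screening threshold for "stable hairpin"; the ceiling sits between the
  73 °C (6-bp stem, high selectivity) and 85 °C (7-bp stem, selectivity
  drops to ~64%) observations: a hairpin that never breathes also slows
  productive cyclization. 4–6 bp stems are flagged `preferred_stem`.

Candidates are ranked by predicted maximum preparative concentration
(the practical quantity), then by more negative $\Delta G$, then by
offset. Rotations failing a rule are reported as near-misses with
per-rule flags, so an unsatisfiable design explains which rule to relax.
The splint is the reverse complement of (last 6 nt ++ first 6 nt) of the
chosen precursor — two 6-nt arms, a 12-nt splint by default.

## Thermodynamic engine

Hairpin structures and energies come from an in-package nearest-neighbor
engine rather than an external folding server, which keeps the tool
self-contained and deterministic:

* **Stems**: unified DNA nearest-neighbor stack parameters (the shipped
  `inst/extdata/nn_unified_v1.json`, version-stamped, overridable by
  file path), perfect Watson–Crick stems only — no wobble pairs, bulges
  or internal mismatches, matching the hairpins the strategy uses.
* **Loops**: tabulated hairpin-loop increments at 37 °C, treated as
  purely entropic ($\Delta S_{loop} = -1000\,\Delta G_{37}/310.15$);
  linear-in-$\log n$ interpolation inside the table and
  Jacobson–Stockmayer extrapolation
  $\Delta G(n) = \Delta G(30) + 2.44\,RT\ln(n/30)$ beyond it. The
  published table has two shallow dips (loop 5 and loop 10, 0.1–0.2
  kcal/mol); they are kept as printed, so the "longer loop never helps"
  property holds as a trend with dips bounded by the table granularity.
* **Ends**: terminal A·T penalty at the open helix end; entropic A·T
  closing-pair adjustment at the loop side.
* **Salt**: the ligase-buffer condition is the default —
  $[\mathrm{Mg}^{2+}] = 10$ mM, 25 °C — folded into an effective
  monovalent concentration $3.3\sqrt{[\mathrm{Mg}^{2+}]}$ and an
  entropy correction $0.368\,N_{bp}\ln[\mathrm{Mon}^+]$.
* **Tm**: unimolecular, $T_m = 1000\,\Delta H/\Delta S - 273.15$;
  undefined (an error) unless both $\Delta H < 0$ and $\Delta S < 0$.

Full minimum-free-energy folding (multiloops, ensembles, partition
functions) is out of scope. Consequently the greedy non-overlapping
structure assignment of `assign_structure()` can differ from an MFE
server's drawing for sequences with competing folds, and absolute
$\Delta G$ values differ from server estimates by a few tenths of a
kcal/mol. The design workflow is robust to this because all rules are
windows, and the equilibrium functions take $\Delta G$ as an explicit
argument, so a user can feed in an external estimate unchanged.

`find_hairpins()` itself is exact for its model: it enumerates every
maximal perfect stem via a pairing-matrix dynamic program and is tested
for set-equality (geometry *and* energies) against a brute-force
triple-loop oracle that reads the parameter JSON independently, on 200
seeded random sequences per run.

## Coordinates and conventions

Sequences are 5′→3′ ACGT; RNA input (`U`) is rejected, not converted.
Reports use 1-based inclusive coordinates; "starts at the 3rd nt" means
two unpaired nucleotides precede the stem, i.e. distance 2. Rotations
are 0-based offsets. Temperatures at interfaces are °C, Kelvin
internally. Enthalpies kcal/mol, entropies cal/(mol·K), concentrations
μM.

## The synthetic test ring

`synthetic_terminal_ring()` builds the 64-nt fixture used in tests and
the acceptance script: a 4-bp GC stem starting at nt 3 of the offset-0
rotation plus a second, internal 4-bp/13-nt-loop hairpin at nt 24 — the
canonical two-hairpin layout for demonstrating the terminal-hairpin
effect — on an all-adenine background. With no T in the sequence, only
G·C pairs can form, so the two designed stems are provably the only
hairpins in any rotation. The terminal hairpin uses a 4-nt loop so that
a 4-bp stem clears the −3 kcal/mol stability rule under this engine
(with an 11-nt loop a 4-bp GC stem scores ≈ −2.7 kcal/mol here); the
positional geometry — the quantity the distance rule is about — is
preserved exactly. It is a synthetic construct, not a sequence from any
published experiment.

```{r}
des <- design_ring(synthetic_terminal_ring(), total_conc = 5)
des$candidates[, c("offset", "side", "distance", "stem_len", "dG", "tm",
                   "max_conc_uM")]
```

## What the random-fragment screen does and does not show

`random_fragments()` draws i.i.d. bases with a set GC probability. The
screen (`Tm > 50` °C, $-\Delta G > 3$ kcal/mol, strict inequalities as
printed) then asks how often an arbitrary sequence already contains a
strategy-usable hairpin. On uniform 50% GC fragments the package finds
qualifying hairpins in roughly a third of 100-nt and under a tenth of
50-nt fragments (seed-dependent), reproducing the *ordering* — longer
fragments are more often usable — that genomic screens show at ~70% vs
~40%. The absolute genomic fractions are not reproducible from random
sequence: genomes are not i.i.d. (repeats, skewed composition,
CpG structure), and the screening engine is not the same estimator as a
folding server. Tests therefore assert the one-sided trend over 600
seeded fragments, not the percentages.

Problem sizes throughout the suite — 200 oracle sequences ≤ 30 nt,
40-rotation invariance on a 40-nt ring, 300 + 300 screening fragments,
1,000 random gel lanes — were chosen as the smallest sets that exercise
each property convincingly while keeping the whole suite fast enough to
run habitually.

## Gel quantification conventions

From band intensities $C$ (circular monomer), $P$ (all polymeric
byproducts, linear and multi-cyclic pooled) and $R$ (remaining
substrate):

$$\mathrm{Conversion} = \Bigl(1-\tfrac{R}{P+C+R}\Bigr)\cdot100,\quad
\mathrm{Selectivity} = \tfrac{C}{C+P}\cdot100,\quad
\mathrm{Yield} = \tfrac{C}{C+P+R}\cdot100.$$

The conversion equation is the standard band-intensity form; the
selectivity and yield definitions follow the ring-fraction-of-ligated-
product convention of the prior literature (the source protocols defer
to earlier papers without restating them; whether remaining substrate
belongs in the selectivity denominator cannot be settled from the
protocol alone, so the definition that makes
$\mathrm{yield} = \mathrm{selectivity}\cdot\mathrm{conversion}/100$ an
exact identity was chosen and is asserted to 10⁻⁹ on random lanes).
Lanes with $C+P=0$ have *undefined* selectivity (`NA`), distinct from 0.
Densitometry — turning a gel image into $C, P, R$ — is out of scope.

## Known limitations

* Perfect-stem model only; G·T wobbles or bulged stems that a folding
  server would report are invisible to the scanner.
* The equilibrium model is thermodynamic; ligation kinetics (the
  observed ~10-fold rate retardation by the hairpin, splint-complex
  stability below 40 °C) are not modeled.
* Buffer-dilution effects on ligase selectivity are experimental
  conditions, recorded only as a free-text `note` in reports.
* The 0.1 μM / >85% anchor is a single calibration point; predictions
  far from it inherit its uncertainty.
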