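---
title: "Force-field topology conversion and its energy-based verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field topology conversion and its energy-based verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amberconv)
```

## The problem

Molecular dynamics and NMR structure-calculation engines each speak their
own topology dialect.  The AMBER ecosystem (antechamber, leap, GAFF)
produces excellent all-atom parameterisations for arbitrary organic small
molecules, but its prmtop/inpcrd files cannot be consumed by GROMACS, CNS
or CHARMM directly: the functional forms, units, sign conventions and
bookkeeping (exclusions, scaled 1-4 pairs, periodic boxes) all differ.
`amberconv` performs those conversions and — crucially — *proves* each one
with a built-in vacuum single-point energy evaluator: the converted
topology must reproduce the source topology's potential energy term by
term.

## The conversion model

All internal state lives in a single container (`molecular_system`) in
AMBER units: kcal/mol, Angstrom, radians, elementary charge.  Conversion
happens at exactly one boundary (the writers and the param-engine
functions), which keeps every transformation individually testable.

| quantity | AMBER convention | GROMACS convention | factor |
|---|---|---|---|
| bond energy | $k (r - r_0)^2$, kcal/mol/A² | $\tfrac{1}{2} k' (r - r_0)^2$, kJ/mol/nm² | $k' = 2 \cdot 4.184 \cdot 100\,k$ |
| angle energy | $k (\theta - \theta_0)^2$, rad | $\tfrac{1}{2} k' (\theta - \theta_0)^2$, $\theta_0$ in deg | $k' = 2 \cdot 4.184\,k$ |
| torsion | $\tfrac{V_n}{2} (1 + \cos(n\phi - \gamma))$, prmtop stores $V_n/2$ | function 9: $k (1 + \cos(n\phi - \phi_s))$ | $k = 4.184 \cdot \tfrac{V_n}{2}$ |
| charge | prmtop stores $q \times 18.2223$ | $q$ in e | $18.2223^2 = 332.05$, the Coulomb constant in kcal·A/mol/e² |
| LJ | like-pair $A = \varepsilon r_{min}^{12}$, $B = 2 \varepsilon r_{min}^{6}$ | $\sigma$ (nm), $\varepsilon$ (kJ/mol) | $\sigma = (A/B)^{1/6}/10$, $\varepsilon = 4.184\,B^2/(4A)$ |

The pinned physical constants (charge scale 18.2223, thermochemical
calorie 4.184, Coulomb constant 332.0522173 kcal·A/mol/e², 1-4 scales 1/2
and 1/1.2) each live in one configuration location shared by writers and
the energy oracle, so emitted defaults and oracle assumptions cannot
drift apart.

## Dihedrals: periodic form first, Ryckaert–Bellemans as an exact option

Multi-term Fourier quartets are emitted as *separate* function-9 lines —
one per component, never combined.  This keeps the exact AMBER analytic
form in the target engine and round-trips losslessly.  An opt-in
Ryckaert–Bellemans path (`dihedral_form = "rb"`) combines a series with
phases restricted to $\{0, \pi\}$ into the polynomial
$\sum_m C_m \cos^m \psi$, $\psi = \phi - 180°$.  Writing
$\cos(n\phi - \gamma_n) = s_n \cos n\phi$ with $s_n = \cos\gamma_n = \pm 1$
and expanding $\cos n\phi$ in powers of $\cos\phi$ gives the closed form

$$C_0 = \tfrac{T}{2} - \tfrac{W_2}{2} + \tfrac{W_4}{2},\quad
  C_1 = -\tfrac{W_1}{2} + \tfrac{3 W_3}{2},\quad
  C_2 = W_2 - 4 W_4,\quad
  C_3 = -2 W_3,\quad
  C_4 = 4 W_4,$$

where $T = \sum_n V_n$ and $W_n$ is the signed amplitude $s_n V_n$
(accumulated over repeated periodicities).  Unlike the commonly tabulated
signed-coefficient shortcut, this form is exact for *every* phase pattern
in $\{0,\pi\}$ — including the constant term — which is what lets the
package assert grid equality at $10^{-9}$ kJ/mol rather than equality up
to an offset.  Phases outside $\{0, \pi\}$ have no RB equivalent and stay
in function-9 form by design.

Improper dihedrals keep AMBER's periodic form as GROMACS function 4; they
are never folded into RB polynomials.  Where the package generates
impropers itself (the MOL2 route), the central atom is placed third and
the outer atoms follow index order; this ordering is a documented package
convention (the quartet ordering conventions of other converters differ,
and the dihedral value is invariant under full reversal in any case).

## 1-4 pairs and exclusions: graph distance, not torsion bookkeeping

GROMACS wants 1-4 interactions listed explicitly as scaled `[pairs]`.
Taking the end atoms of every proper torsion over-counts in rings: a
hexagon has six torsion paths but only three para pairs, and in a
4-membered ring every torsion's end pair is simultaneously 1-2 or 1-3
connected.  The package therefore defines a 1-4 pair as *a pair of atoms
at bond-graph distance exactly three*, uses torsion `generates_14` flags
only as an additional mask, and deduplicates.  Tests compare the result
against an independent shortest-path oracle on every fixture.  Exclusion
lists cover all 1-2/1-3/1-4 neighbours symmetrically.

## Boxes

A truncated octahedron with edge $d$ (all inpcrd angles
$\arccos(-1/3) = 109.4712°$, matched within $10^{-4}$ degrees) maps to the
GROMACS triclinic orientation
$a = (d, 0, 0)$, $b = (-d/3, \tfrac{2\sqrt 2}{3} d, 0)$,
$c = (-d/3, -\tfrac{\sqrt 2}{3} d, \tfrac{\sqrt 6}{3} d)$; all three
vectors have norm $d$ and all mutual angles equal $\arccos(-1/3)$.
Orthorhombic boxes become diagonal matrices.  Systems without a box get a
rectangular cell from the coordinate extent plus twice a clearance per
axis; the clearance default is 1.0 nm — a conventional solvation margin —
and is configurable.

## Water recognition

TIP3P and SPC/E are recognised by *physics*, not residue names: a 3-atom
O/H/H residue matches a model when its charges agree within $10^{-3}$ e
and the oxygen $\sigma$/$\varepsilon$ within $10^{-3}$ relative against a
versioned plain-text reference table (`extdata/water_models.txt`).
Name-independent matching survives renamed residues; the tolerance is
tight enough that the two models (whose charges differ by 0.014 e) can
never cross-match.  The recognised model is reported in the topology
header and run manifest; the numeric parameters are still written
explicitly so every emitted file stays self-contained and re-parseable.

## Input screening and charge handling

Bonded pairs closer than 0.5 A or farther than 3.0 A almost always
indicate corrupt input structures, so conversion aborts on any such bond,
naming the rule (`min_0.5` / `max_3.0`).  The net charge is
`round(sum(q))`; a residual above 0.01 e warns (typical charge-derivation
drift), above 0.1 e the guess is refused — a deviation that large means
the charge column cannot be trusted.  Charge *computation* (AM1-BCC via
sqm, Gasteiger) is delegated to an external antechamber when one is
configured; without it the MOL2 user-charge route and the prmtop route
are fully self-contained.

## The energy oracle

`single_point_energy()` evaluates bonds, angles, torsions and all-pairs
nonbonded terms (no cutoff, no periodicity) in either the AMBER form or
the re-parsed GROMACS form, normalising to kJ/mol.
`compare_conversion()` writes the topology, re-reads it with the
package's own GROMACS parser and compares the two energy reports term by
term; any relative difference above $10^{-6}$ is flagged.  Design points:

* Vacuum, no-cutoff evaluation is exact and engine-independent; the
  oracle certifies *topology conversion*, not simulation realism.
* Both forms are evaluated at the same coordinates (Angstrom exactly
  scaled to nm).  `.gro` files carry only three decimals in nm by format;
  evaluating the converted side at file-precision coordinates would
  measure coordinate rounding, not conversion fidelity.
* Dihedral angles use the standard signed IUPAC convention (cis = 0).
* Overlapping non-excluded atoms (r < $10^{-6}$ A) are an error naming
  the pair, since the LJ term is about to overflow.
* Parameters are printed with 10 significant digits (fixed format, so
  output is byte-deterministic across platforms); that keeps worst-case
  parameter rounding near $10^{-10}$ relative, three orders below the
  fidelity tolerance.

## What the toy fixtures do and do not show

`generate_toy_system()` builds four small molecules fully in code — a
TIP3P water, methane, a 4-atom carbon chain with one torsion, and a bare
aromatic 6-ring with an improper — each with a seeded coordinate jitter
(at most 0.02 A per component; bond lengths stay within 0.9–1.6 A).  The
accompanying parameter tables are *synthetic*: values sit in plausible
general-force-field ranges but are defined by this package
(`extdata/gaff_subset_synthetic.frcmod` is generated from the same
in-code table).  The fixtures exercise every conversion mechanism —
zero-LJ hydrogens, multi-path ring 1-4 deduplication, improper encoding,
fixed-width IO — at sizes (3–6 atoms) where the exact energy oracle runs
in milliseconds.

Passing tests therefore certify the *conversion machinery*: parsing,
unit/form transformations, pair generation, writers and the energy
equality.  They do not certify force-field accuracy for real molecules —
atom typing and charge derivation are upstream of this package — and the
published comparison of converted amino-acid topologies against a native
GROMACS force-field port requires external AmberTools and GROMACS
installations, which is why that benchmark is not part of the default
suite.

## Numerical and interface choices

* Canonical parameter keys use C-locale (radix) collation so lookup
  tables and emitted files are identical across locales.
* Wildcard torsion matching order is exact > single-X > double-X within
  each source, mirroring AMBER matching practice; sources are consulted
  in priority order (e.g. protein force field before GAFF), and each
  resolved term records its provenance label.
* Duplicate frcmod keys: last entry wins, with a warning.
* CNS output uppercases all atom/type names (CNS rejects mixed case) and
  uses a sigma-based NONBonded convention with the 1-4 epsilon pre-scaled
  by 1/2; since no CNS reader exists in-repo, these files are checked by
  a statement-grammar validator, while energy fidelity is certified on
  the GROMACS path that shares every upstream conversion.
* CHARMM output is the rtf/prm pair only; psf generation belongs to
  CHARMM.  Bonded constants pass through unchanged (CHARMM shares
  AMBER's no-half-factor convention); LJ becomes $-\varepsilon$ with
  $R_{min}/2 = \sigma\,2^{1/6}/2$.
* Fixture seeds default to 42; nothing depends on the wall clock, and
  identical inputs produce byte-identical outputs (asserted by double
  invocation).

## Known limitations

* Recognised waters are annotated, not rewritten into engine-bundled
  `#include` topologies with SETTLE; emitting those would break the
  self-contained re-parse guarantee the oracle relies on.
* General triclinic cells outside the orthorhombic/truncated-octahedron
  kinds are rejected explicitly rather than guessed.
* NetCDF restarts, CHAMBER-style prmtop variants, polarisable terms,
  Urey-Bradley/CMAP and virtual sites are out of scope.
* PDB/MDL input requires an external structure-conversion tool; MOL2 and
  prmtop/inpcrd routes never do.
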