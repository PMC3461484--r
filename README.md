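# amberconv

AMBER small-molecule topology conversion with built-in energy
verification.

## The problem

All-atom force-field parameterisations for arbitrary organic small
molecules are routinely produced in the AMBER ecosystem (antechamber /
leap with GAFF or the AMBER protein force fields), but the resulting
prmtop/inpcrd files cannot be used directly by GROMACS, CNS/XPLOR or
CHARMM.  The engines differ in functional forms, units and bookkeeping:

* AMBER writes harmonic terms as *k*(x − x₀)² in kcal/mol with
  Angstrom/radian arguments; GROMACS uses ½*k*(x − x₀)² in kJ/mol with
  nm/degree arguments (a factor 2·4.184·100 on bond constants).
* AMBER dihedrals are Fourier series (*V*ₙ/2)(1 + cos(*n*φ − γ)), with
  the half-barrier stored and proper/improper/1-4 information encoded in
  index sign flags; GROMACS wants explicit per-component periodic lines
  (function 9), periodic impropers (function 4), or Ryckaert–Bellemans
  polynomials.
* prmtop charges are stored as *q* × 18.2223 (so 18.2223² is the Coulomb
  constant in kcal·Å/mol/e²); Lennard-Jones interactions as like-pair
  A/B coefficients rather than σ/ε.
* 1-4 interactions must be listed explicitly as scaled pairs (LJ ÷ 2,
  Coulomb ÷ 1.2), deduplicated correctly in rings; truncated-octahedron
  boxes (all angles arccos(−1/3) ≈ 109.47°) must become triclinic
  vectors.

`amberconv` reads the AMBER-side formats (prmtop, inpcrd, Tripos MOL2,
frcmod/parm-dat), performs all of these conversions, writes GROMACS
(.top/.gro), CNS (topology/parameter/run-input) and CHARMM (rtf/prm)
files, and **certifies every conversion with a vacuum single-point
energy evaluator**: the re-parsed converted topology must reproduce the
source topology's potential energy term by term (bonds, angles, propers,
impropers, scaled 1-4 LJ/Coulomb, nonbonded LJ/Coulomb) within 1 part in
10⁶.

It is aimed at structural-bioinformatics and molecular-modelling users
who need ligand topologies moved between engines — and at anyone who
wants the move *proved* rather than assumed.

## Worked example

Convert a prmtop/inpcrd pair (here: the bundled 4-atom chain fixture
with one torsion) to GROMACS and verify the conversion:

```r
library(amberconv)

toy <- generate_toy_system("chain4", seed = 42)
writeLines(toy$prmtop, "chain4.prmtop")
writeLines(toy$inpcrd, "chain4.inpcrd")

res <- run_amb2gmx("chain4.prmtop", "chain4.inpcrd", out_dir = "chain4.amb2gmx")
print(res$system)
print(res$fidelity$per_term, digits = 4)
```

```
<molecular_system> toy chain4
  atoms: 4   bonds: 3   angles: 2   torsions: 1 (0 improper)
  coordinates: present   box: none   net charge: 0
        term     source  converted  rel_diff flagged
1      bonds  0.7925162  0.7925162 2.788e-14   FALSE
2     angles  0.0496747  0.0496747 9.695e-09   FALSE
3    propers  0.0001817  0.0001817 1.492e-16   FALSE
4  impropers  0.0000000  0.0000000 0.000e+00   FALSE
5      lj_14  2.2011053  2.2011053 1.624e-10   FALSE
6 coulomb_14 -3.8626353 -3.8626353 4.000e-11   FALSE
7      lj_nb  0.0000000  0.0000000 0.000e+00   FALSE
8 coulomb_nb  0.0000000  0.0000000 0.000e+00   FALSE
9      total -0.8191573 -0.8191573 8.357e-10   FALSE
```

The `source` column is the single-point energy (kJ/mol) evaluated on the
AMBER-form system; `converted` is the same energy evaluated on the
emitted-and-re-parsed GROMACS topology; `rel_diff` is their per-term
relative difference.  The worst term here differs by about 1 part in
10⁸, far inside the 10⁻⁶ certification gate.  `chain4.amb2gmx/` now
contains `MOL_GMX.top`, `MOL_GMX.gro` and a manifest recording the
recognised water model (none here), computed box and fidelity result.

The MOL2 route with user charges runs the full pipeline (geometry
screening, net-charge check, parameter resolution with source fallback,
all writers):

```r
cfg <- run_config("ligand.mol2", charge_mode = "user",
                  param_files = "ligand.frcmod")
res <- run_convert(cfg)
```

A thin command-line wrapper ships in `inst/scripts/amberconv`
(`amberconv -i ligand.mol2 -c user`, `amberconv -p x.prmtop -x x.inpcrd`,
`amberconv --energy -p x.prmtop -x x.inpcrd`); exit codes distinguish
input (2), geometry (3), parameter (4), external-tool (5) and timeout
(6) failures.

## Scope notes

Charge *computation* (AM1-BCC, Gasteiger) is delegated to an external
antechamber when configured; the MOL2 user-charge and prmtop routes are
fully self-contained.  The bundled parameter file
`inst/extdata/gaff_subset_synthetic.frcmod` is a synthetic subset
covering the toy fixtures only.  See the vignette
(`vignettes/topology-conversion.Rmd`) for the conversion model,
numerical choices and limitations.
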