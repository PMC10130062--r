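---
title: "Models and methods behind minimet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind minimet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimet)
```

`minimet` packages two things: a symmetry-guided miniaturization workflow for
tetrathiolate metalloproteins, and the structural/biophysical analytics used
to validate such a design. This vignette explains the models, the tunable
parameters and their defaults, the numerical conventions, what the synthetic
generators do and do not emulate, and the known limitations. Every number
quoted here is computed by the package's tests or examples; nothing is copied
in by hand.

## Structures and geometry

A structure is a tibble with one row per atom (`record`, `elety`, `resid`,
`chain`, `resno`, `x/y/z` in Å, `o`, `b`, `elesy`) plus attributes for the
unit cell, space group and symmetry operators. PDB and mmCIF reading is
delegated to bio3d; the CRYST1 record and mmCIF symmetry loops are parsed
directly because bio3d does not surface them. Alternate locations collapse to
the highest-occupancy conformer (ties: first encountered) so every downstream
measurement sees one atom per site. Writing emits fixed-width PDB records to
three decimals, which bounds round-trip coordinate error at 5e-4 Å.

Symmetry expansion applies every operator with lattice translations of ±1
cell along each axis and keeps mates with any atom inside the search radius.
Operators for P1, P21, C2221 and P212121 ship built in; anything else must
arrive via an mmCIF symmetry block or explicit operators. Fractional ↔
orthogonal conversion uses the crystallographic orthogonalization matrix with
*a* along x (the PDB convention). Mates are exact rigid copies — the tests
check pairwise-distance preservation at 1e-6 Å.

Superposition is the Kabsch SVD solution restricted to proper rotations
(det = +1), cross-checked in the tests against `bio3d::fit.xyz` and against
200 random rigid transforms per case (optimality). Dihedrals follow the IUPAC
convention in (−180°, 180°]: cis = 0, trans = 180, sign flips under mirror
reflection and — deliberately — *not* under atom-order reversal, since the
torsion of D–C–B–A equals that of A–B–C–D. Cys χ1 is the N–CA–CB–SG torsion;
rotamer classes use g+ ↦ +60°, t ↦ 180°, g− ↦ −60° with boundaries at 0° and
±120°. The literature is split on the g+/g− naming; this mapping is fixed
here and used consistently.

Backbone RMSD defaults to N/CA/C/O (a `CA`-only or custom atom set is an
argument) because published "backbone RMSD" figures rarely state the atom
list; the difference between conventions is well under the 0.05 Å tolerance
used in the tests.

## Miniaturization: dissect, C2, close, graft

`dissect()` deep-copies a contiguous author-numbered range and refuses gaps
or incomplete backbones. `fit_c2_axis()` maps one half-site onto the other by
Kabsch and converts the rotation to axis-angle form; the angle is reported as
a *diagnostic* of how far the template deviates from exact twofold symmetry,
and `make_c2_dimer()` always applies an exact 180° rotation about the fitted
axis (design needs exact symmetry; the deviation is reported, not
propagated). A metal, when present, is kept once and projected onto the axis.
Interchain heavy-atom pairs closer than 2 Å raise a warning, not an error —
a clashing dimer is a legitimate intermediate to inspect.

The loop search counts **gap length** as the number of intervening residues,
excluding the two matched anchors, so a window spans gap + 2 residues; a
four-residue gap is exactly one β-turn flanked by the anchors. Both anchors'
N/CA/C/O (8 atoms) are fitted jointly in one rigid superposition — the
standard two-ended closure criterion — and windows with post-fit RMSD at or
below the cutoff (default 1.0 Å) become hits. One residue per side is
matched; windows straddling chain breaks (non-consecutive numbering or
peptide C–N over 1.8 Å) are skipped and counted. Grafting renumbers
chain 2 + loop + chain 1 from 1, keeps scaffold coordinates at the anchors,
and enforces peptide-bond sanity at both junctions: outside [1.2, 1.45] Å a
geometry warning is attached; above 2.0 Å the hit is ungraftable and the call
fails.

Published hit counts from fragment searches (totals per gap length, turn-type
tallies) depend on the library version used and are not reproducible from a
bundled fixture; the package instead *plants* loops of known gap length and
turn type in synthetic libraries and requires the search to recover them, and
the turn census to reproduce the planted composition. That validates the
machinery, not any specific library survey.

## Turn typing and motifs

β-turns are classified by the nearest canonical (φ, ψ) of the two central
residues — I: (−60,−30,−90,0); I′: (60,30,90,0); II: (−60,120,80,0);
II′: (60,−120,−80,0); VIII: (−60,−30,−120,120); III: (−60,−30,−60,−30);
III′: (60,30,60,30) — with all four angles within ±30° (one may deviate up to
±45°), else type IV; a Cα(i)–Cα(i+3) distance over 7 Å means "not a turn".
Types III/III′ are kept separate from I/I′ (modern schemes absorb them)
because the turn census distinguishes them; when both qualify, the smaller
summed angular deviation wins, with exact ties resolved to the 3₁₀-like type
only when ψ(i+2) deviates from 0° by more than 25°. No i→i+3 hydrogen bond is
required — open turns found by loop searches would otherwise be missed. The
exact tolerances used in the original design work are not published; these
are the classical survey defaults, and the round-trip property (build a
backbone from canonical dihedrals of each type, re-measure, re-classify) is
tested for all seven types, as is the mirror mapping I↔I′, II↔II′, III↔III′.

Backbone H-bonds use the classical electrostatic criterion
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with a −0.5
cutoff; amide H atoms are built geometrically (1.0 Å from N, opposite the
bisector of N→C(prev) and N→CA; prolines and N-termini skipped). Motif labels
derive from the bond pattern: two or more consecutive i→i+3 bonds mark a 3₁₀
stretch, an isolated i→i+4 bond an α-turn, mutual donor/acceptor pairs mark
antiparallel bridges, and a bridge pair offset by one extra residue on one
strand marks a β-bulge. This is the motif vocabulary needed for a miniature
metal-binding fold, not a full DSSP reimplementation.

## Metal-site analytics

`find_metal_site()` takes the single atom of the requested element (or an
explicit serial) and collects donor atoms within 2.8 Å (thiolate and other
common O/N donors); non-4-coordinate sites are flagged rather than rejected.
First-shell geometry reports all four distances, six angles, the two
Sγ–M–Sγ–Cβ torsions across the pseudo-dyad (ligand pairs taken as 1–3 and
2–4 in residue order), per-Cys χ1 classes, and a tetrahedricity score (RMS
angular deviation from 109.47°). Reference z-scores use the bundled
ultrahigh-resolution Zn-rubredoxin survey statistics (2.34 ± 0.03 Å,
109 ± 4°); the database query behind that survey is version-dependent and is
not re-run.

NH···S hydrogen bonds to sulfur need longer cutoffs than to oxygen: defaults
are donor–S ≤ 3.6 Å, H···S ≤ 2.9 Å, D–H···S angle ≥ 120° for backbone
amides, and the heavy-atom distance criterion for side-chain donors
(Asn/Gln amides, Arg guanidinium, Ser/Thr/Tyr hydroxyls). All three
thresholds are arguments; detection is monotone in them (loosening never
removes a bond), which the tests exercise. Crystal contacts pair the
molecule against its symmetry mates: Arg/Lys N⁺ to Asp/Glu O⁻ at ≤ 4.0 Å is
a salt bridge, polar–polar pairs within 3.6 Å are hydrogen-bond contacts,
anything else within the radius is a generic contact.

## EPR: rhombograms and rhombicity

For a high-spin ferric ion (S = 5/2) the zero-field-splitting Hamiltonian
H = D[S_z² − S(S+1)/3] + E(S_x² − S_y²) splits the sextet into three Kramers
doublets. The intra-doublet resonances are described by effective g values
that depend only on E/D and the intrinsic g0 — the rhombogram.
`zfs_effective_g()` evaluates them numerically: the 6×6 complex Hermitian
matrix is diagonalized with a Zeeman term g0·μB·B·S_k added along each axis,
and B is halved until every g_eff changes by less than 1e-4 (the weak-field
limit; finite-field checks at X-band shift these values by under 0.01 for
D between 1 and 2.5 cm⁻¹, so the limit is safe for this system). The
closed-form anchors are tested exactly: at E = 0 the doublets give
g_z = {2, 6, 10}·(g0/2) with the ground doublet at (6, 6, 2), and at
E/D = 1/3 the middle doublet is isotropic at 30/7 ≈ 4.29.

`estimate_rhombicity()` scans E/D over [0, 1/3] (step 0.001, D > 0,
g0 = 2.0023 — the standard choice for high-spin Fe³⁺ effective-g work) and
minimizes the summed distance between each observation and its nearest
doublet component. **Known limitation:** for the classic observation pair
{9.15, 4.26} this objective is nearly flat between E/D ≈ 0.21 and 0.30 and
its minimum sits at 0.267, with 9.15 matched to the ground-doublet g_y and
4.26 to the middle-doublet g_x. Reading only the sharp low-field line
(g_y = 9.15) off the rhombogram gives E/D ≈ 0.205. Published "about 0.22"
values for such spectra are rhombogram readings dominated by the 9-region
line; the g ≈ 4.3 feature of the middle doublet is broad and nearly
stationary in position, so it constrains E/D weakly. The estimator is kept
as the plain symmetric objective — it is the defensible automatic choice —
and this discrepancy is documented rather than tuned away.

## Electrochemistry

`analyze_voltammogram()` splits a cycle at the sweep turning point, optionally
applies Savitzky–Golay smoothing (tested not to move ideal peaks by more than
1 mV) and a linear baseline, picks the anodic/cathodic extrema, and reports
E_pa, E_pc, i_pa, i_pc, E_half = (E_pa + E_pc)/2 + offset and ΔE_p. The
reference offset converts to SHE (+0.206 V for Ag|AgCl 3 M NaCl). A flat
trace is flagged "no peaks", not an error. The synthetic trace generator
places Gaussian anodic/cathodic waves ±29.5 mV around the formal potential —
the Nernstian one-electron separation at 25 °C — so peak positions are exact
by construction; it emulates peak positions and scan-rate scaling, not the
true diffusional waveshape or capacitive background of a measured
voltammogram.

`randles_sevcik_fit()` regresses |i_p| on √ν with zero intercept and converts
the slope through i_p = 0.4463·n·F·A·C·√(nFνD/RT) to the diffusion
coefficient, with the standard error propagated from the slope (ΔD/D =
2Δs/s). Noise-free synthetic peaks are recovered to 1e-9 relative; at 2%
current noise over the experimental scan-rate range (2.5–50 mV/s, 80 µM,
3 mm electrode, 288 K) the median relative error on D stays below 5% across
100 seeds.

## Binding, optics, hydrodynamics

The 1:1 isotherm uses the exact quadratic complex concentration
[PL] = ((P+L+K_D) − √((P+L+K_D)² − 4PL))/2, fitted by bounded
Levenberg–Marquardt over (K_D, ε_complex, baseline). The fit runs in units of
the protein concentration so all parameters are O(1) — micromolar-scale K_D
values otherwise underflow the numeric Jacobian — and a K_D collapsing to the
zero bound is flagged as an upper limit: when K_D ≪ P (e.g. 300 nM against a
30 µM titration) the data bound K_D from above rather than pin it, which is
why such experiments are reported as "K_D ≤ …". The stoichiometric limit
(K_D = 0) breaks at exactly 1.0 equivalent, located by intersecting the
rising and plateau line fits.

ε280 = 5500·nTrp + 1490·nTyr + 125·nCystine; Aib (coded "X") does not absorb.
Beer–Lambert conversion takes ε in mM⁻¹cm⁻¹ and returns µM.

Translational diffusion uses the Kirkwood bead approximation with one bead
per heavy atom (radius 3.1 Å): D_t = (k_BT/N)[1/(6πησ) +
(1/(6πηN))·Σ_{i≠j} 1/R_ij], verified against the one-bead (Stokes–Einstein)
and two-bead closed forms and monotone-decreasing for growing rigid bodies.
Temperature and viscosity are explicit (288 K and 1.138 mPa·s — 15 °C water —
match the voltammetry conditions). **Known limitation:** with ~200 beads the
self term is ~500-fold smaller than the pair term, so the bead radius (and
hence hydration) barely enters, and D is set by the harmonic mean of
inter-atomic distances alone. For any compact ~3 kDa protein envelope this
point-bead sum gives ≈ 2.0–2.3×10⁻⁶ cm²/s, roughly 40–50% above what
bead-shell programs with hydrated atomic radii (the HYDRONMR family) predict
for the same coordinates. The formula is implemented exactly as stated and
the discrepancy is documented; matching shell-model output would require the
Rotne–Prager tensor and a shell extrapolation, which is out of scope.

## Synthetic generators: what they do and do not show

All fixtures are built in code, deterministically under a seed.

* `make_ideal_site()` places four Sγ at exact tetrahedral vertices
  (default M–S 2.34 Å) with Cβ set to prescribed Sγ–M–Sγ–Cβ torsions
  (default 180° and 159° for the 2/17 and 5/20 ligand pairs). It is the
  survey-geometry reference the first-shell code is validated against.
* `backbone_from_dihedrals()` builds chains by sequential internal-coordinate
  placement (N–CA 1.458, CA–C 1.525, C–N 1.329 Å, ideal angles,
  L-chirality Cβ); re-measured dihedrals match the inputs to better than
  1e-3°.
* `make_mini_library()` writes decoy chains whose dihedrals are sampled from
  broad β (φ ∈ [−150,−90], ψ ∈ [110,150]) and α (φ ∈ [−70,−50],
  ψ ∈ [−50,−30]) basins — kept away from turn geometries so false positives
  at tight cutoffs are essentially absent — and splices canonical turn
  windows in as internal coordinates, so planted chains stay continuous.
  `make_closure_scaffold()` builds the matching open scaffold whose stub pair
  coincides exactly with the planted window's anchors: search must recover
  the plant at ~0 anchor RMSD and grafting must give 1.329 Å junctions.
* `synthetic_metpsc1()` is a 28-residue single-chain surrogate of a miniature
  ZnCys4 protein: two 13-residue units (strand / metal-binding α-turn /
  strand / 3₁₀ stretch / strand) joined by a Gly–Gly type I′ turn, built as
  one continuous chain from a frozen dihedral program. The free torsions and
  Cys χ1 were fixed once by an offline geometric optimization for a
  tetrahedral Sγ cluster, no backbone clashes, and a compact envelope
  (backbone R_g ≈ 7.8 Å), and are constants of the generator. Its site is
  deliberately *not* idealized (Sγ cluster 0.44 Å RMSD from ideal vertices,
  mean Zn–S 2.71 Å) and its two units are only loosely pseudo-symmetric
  (relating rotation ≈ 129°) — good enough to exercise dissection, axis
  fitting, annotation and hydrodynamics on a realistic whole molecule, but
  not a substitute for a refined crystal structure. Side chains beyond Cβ are
  reduced to pseudo-atoms along the Cα→Cβ direction so the molecular envelope
  is mass-realistic.
* `synthetic_design_pair()` returns the surrogate and a copy whose optimal
  backbone RMSD equals a requested value exactly (seeded displacements
  rescaled by root finding, then an arbitrary rigid motion) — the fixture for
  design-vs-experiment RMSD readback.
* `synthetic_c2221_crystal()` places partial Tyr/Arg/Asp/Cys residues in a
  C2221 cell so that specific mate contacts appear at prescribed distances
  (Tyr OH···OH at 3.32 Å, an Arg–Asp salt bridge, a guanidinium···Sγ
  hydrogen bond under the (−x, y, −z+½) operator).
* `make_measurements()` generates titrations (defaults: 30 µM protein,
  26 points to 2.5 equivalents), voltammetry peak tables (80 µM, 2.5–50 mV/s,
  288 K, 3 mm glassy-carbon electrode) and effective-g observation sets
  (default E/D 0.22, g0 2.0023, the ground-doublet g_y and middle-doublet g_x
  components), with seeded relative Gaussian noise.

Passing tests on these fixtures demonstrates that the algorithms recover what
was planted under realistic geometry and noise. They do not demonstrate
performance on experimental data: real structures have non-ideal bond
geometry, alternate conformers and solvent; real libraries have PDB
composition statistics; real voltammograms have capacitive backgrounds. No
deposited coordinates are bundled — every structural fixture is synthetic and
labelled as such.

## Problem sizes and determinism

The test suite uses small, fixed problem sizes chosen to exercise every code
path: libraries of 1–10 chains of ~30 residues, 15–60 seeds for the
simulation bands, a 0.001 E/D grid for the headline rhombicity scan and
0.005 elsewhere. All randomness is seeded locally (generators save and
restore the RNG state), so identical calls give byte-identical output, which
the suite checks by comparing generated library files byte for byte.
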