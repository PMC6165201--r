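---
title: "Methods: peptaibol mass chemistry, de novo sequencing and ensemble statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptaibol mass chemistry, de novo sequencing and ensemble statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptaibio)
```

## The problem

Peptaibols are linear, non-ribosomal fungal peptides with three structural
hallmarks: an acetylated N-terminus, a C-terminal 1,2-amino alcohol, and a
high content of the achiral helix-former alpha-aminoisobutyric acid (Aib),
often together with isovaline (Iva). A strain's *peptaibiome* is typically
profiled by HPLC-ESI-MS: each compound is recognised from a small set of
characteristic ions -- the sodiated precursors [M+Na]^+^ and [M+2Na]^2+^, the
N-terminal acylium fragment b~12~ and the C-terminal fragment y~7~ (the
latter only visible after MS^2^) -- and its residue sequence is read from the
b-ion ladder. This package implements that workflow end to end: the residue
mass chemistry, the de novo assembly from peak lists, annotation against
known peptaibols, external-standard quantitation, and the
conformational-ensemble statistics used to characterise peptaibol backbones
(Ramachandran free-energy surfaces, backbone hydrogen bonding, RMSD and
radius-of-gyration landscapes).

## Mass chemistry

Residue masses are residue (amino acid minus water) masses built from
monoisotopic atomic constants (H 1.007825, C 12, N 14.003074, O 15.994915,
Na 22.989770, electron 0.000549); average masses use the IUPAC 2021 standard
atomic weights. The neutral mass of an acetyl-capped amino-alcohol peptaibol
is

$$ M = \sum_i m_i + 18.01056 + 42.01057 - 13.97926, $$

where the last term is the reduction of the terminal carboxyl to the
1,2-amino alcohol (-O +2H); in the implementation that correction is carried
by the alcohol residue's own formula. Fragment series follow the standard
conventions for this compound class:

* b~n~ (acylium): $\sum_{i \le n} m_i + 42.01057 + 1.00728$,
* y~k~ (protonated C-terminal): $\sum_{i > n-k} m_i + 18.01056 - 13.97926 + 1.00728$,

with the complementarity identity $b_{n-k} + y_k - M = 2 \times 1.00728$
holding for every split. Sodiated adducts use the Na^+^ cation mass
22.98922 (atomic Na minus one electron).

Because an ion trap at unit resolution cannot separate Leu from Ile or Val
from Iva (identical residue formulas), the package treats the isobaric
classes `Lxx`, `Vxx` and `Lxxol` as first-class sequence tokens; all
sequencing output and database comparison happen at this class resolution,
with a `strict` mode available.

**Tolerance policy.** The published compound tables were read from an ion
trap and mix monoisotopic with isotope-apex peaks: compounds with identical
class sequences are printed with masses scattered over roughly 1 Da (e.g.
two positional isomers printed at 1890.2 and 1889.3). Theoretical
comparisons against printed table values therefore use a +-1.0 Da window in
general, tightened to +-0.25 Da for the rows that were verified explicitly
(the b~12~ 1122.5 and M 1889.3 of the trikoningin-matching compounds).

## De novo sequencing

`assemble_sequence()` runs four stages, each available separately:

1. **Adduct deconvolution** (`deconvolute_adducts`). [M+Na]^+^ is inverted to
   M; when [M+2Na]^2+^ is also present it provides a cross-check, and the
   two implied neutral masses must agree within twice the matching
   tolerance.
2. **b-ladder walking** (`walk_b_ladder`). Consecutive differences of the
   ascending b series are matched to single residues or two-residue
   composites. The 213.11 Da difference -- the Gln-Aib block whose amide
   bond survives ion-trap fragmentation -- is expanded only in its motif
   order Gln-then-Aib. b~1~ is assumed absent (a single-residue acylium is
   rarely observed), so the first observed peak may be any b~n~ with
   n <= 3, resolved by composite enumeration against the acetyl+proton
   offset. Gaps wider than two residues end the walk; those positions fall
   to the later stages.
3. **y~7~ family resolution** (`resolve_y7`). All compounds of this class
   share the C-terminal scaffold Pro13-Vxx14-Aib15-X16-Gln17-Z18-Lxxol19;
   the observed y~7~ m/z selects one of the four families
   (X16 in {Lxx, Vxx}) x (Z18 in {Gln, Glu}) by nearest-variant matching
   (the families are ~14 and ~1 Da apart, so a 0.5 Da decision boundary
   separates Gln/Glu cleanly at the simulated noise levels). MS^2^ sub-ions
   refine positions 16-19 when present. Positions 13-15 are never called
   from y~7~: the corresponding internal ions are not observed.
4. **Motif fill and closure** (`fill_motif`). b~14~ is suppressed after the
   Aib12-Pro13 bond, so positions 13-15 are predicted from the conserved
   Aib-Pro-Vxx-Aib motif (Pro13, Vxx14, Aib15, provenance `"motif"`);
   observed calls are never overwritten and contradictions raise an error.
   Finally the called sequence must close the observed neutral mass within
   the tolerance for the assignment to be `complete`.

Every position carries a provenance tag (`ladder`, `ms2`, `motif`,
`closure`, `unresolved`), so a reader of the report can see which calls are
measured and which are scaffold- or motif-inferred.

**Sequencing alphabet.** Matching uses a restricted peptaibol alphabet
(Gly, Ala, Ser, Pro, Vxx, Thr, Lxx, Asn, Asp, Gln, Glu, Aib, Phe, Tyr, Trp)
rather than the full residue library. The minimum pairwise mass gap in this
alphabet is 0.98 Da (Gln/Glu, Asn/Asp), so nearest-mass matching is
essentially error-free at the simulated 0.05 Da centroid noise; the full
library would add Lys at 0.036 Da from Gln, which unit-resolution data
cannot separate. The alphabet is an explicit argument for users working on
other compound classes.

**Candidate ranking.** Ambiguous expansions (isobaric composites such as
Aib+Gly = Ala+Ala, or both orders of a two-residue jump) are enumerated and
ranked by: fewer unresolved positions, fewer composite jumps, smaller
absolute closure residual (compared at 1e-6 Da so exactly isobaric
candidates tie), an N-terminal Aib preference (every known compound of this
class starts Ac-Aib; this resolves the head ambiguity created by the
missing b~1~), and finally the lexicographic token string, which makes the
result deterministic and independent of input peak order.

**Defaults.** The matching tolerance defaults to 0.6 Da, appropriate for a
unit-resolution ion trap. Position 17 is fixed as Gln for the 19-residue
scaffold (universal in this compound family), overridable by MS^2^
evidence; its provenance is `closure` when not directly observed.

## Annotation and naming

`compare_peptaibols()` compares two equal-length sequences position-wise at
class resolution: identical everywhere gives `identical_by_class`; equal
multisets in a different order give `positional_isomer`; otherwise the
per-position exchange list $[X]^i \to [Y]^i$ (database token to query
token) is reported. Different lengths are reported as such, never scored.
`annotate_against_db()` ranks database entries by relation class, then
exchange count, then name, and flags the query `new` when no
identical-by-class hit exists.

The packaged known-peptaibol database was reconstructed from the printed
per-position exchange records of the source tables (the tables do not print
the comparison sequences themselves); where several rows cite the same
entry the mutually consistent majority reconstruction was used, and the
packaged `expected_relations.tsv` documents, row by row, where the printed
records contradict the printed query sequences. One 18-residue entry is a
synthetic stand-in (marked as such) to exercise different-length handling.

`assign_names()` implements the elution-order nomenclature: compounds are
sorted by retention time and numbered I, II, ...; co-eluting compounds that
differ in their characteristic-ion family share a numeral with letters a,
b, ... in ascending y~7~ mass. Operationally a cluster is a maximal
elution-ordered run whose consecutive members are within `cluster_window`
minutes and strictly ascend in y~7~ family (families are distinguished
above 0.5 Da, i.e. at least a Gln/Glu step). The default window is 1.2 min:
the largest printed within-pair gap in the reference table is 1.141 min and
the rule reproduces all 19 printed labels, including the singleton that
elutes only 0.4 min before the following pair but carries the higher y~7~
family. The letter-ascends-with-y7 convention follows the larger of the two
published tables; the second table contains one pair labelled in the
opposite order, which this rule does not reproduce -- a documented
limitation.

## Quantitation

`fit_calibration()` fits concentration = response_factor x area by least
squares through the origin -- the model a single external standard
(alamethicin) supports; one factor is applied to all compounds since a
single standard cannot give compound-specific response. Relative
composition is the area share normalised to 100%. The accuracy flag encodes
the length rule for single-standard quantitation of this compound class:
only 17-20-residue peptaibols are flagged `accurate`; shorter (11-14
residue, Pro-rich) peptaibols have structurally different response and are
flagged `low_accuracy`. Reproducing the study's absolute contents
(micrograms per millilitre of crude extract) is out of scope: the raw
chromatogram areas behind them are not published.

## Conformational-ensemble statistics

Ensembles are multi-model PDB files (MODEL/ENDMDL) with backbone atoms N,
CA, C, O and optionally the amide H; frames share one topology.

* **Dihedrals.** Phi(C$_{i-1}$, N$_i$, CA$_i$, C$_i$) and Psi(N$_i$,
  CA$_i$, C$_i$, N$_{i+1}$) in the IUPAC sign convention (verified against
  an independent implementation), undefined at the termini.
* **Free-energy surfaces.** $\Delta G = -RT \ln(P / P_{max})$ with
  R = 1.9872e-3 kcal mol^-1^ K^-1^ and T = 300 K by default (the
  thermostat temperature of the reference simulations); the minimum over
  occupied bins is exactly 0 and empty bins are masked rather than set to
  infinity. Ramachandran surfaces default to 72 x 72 bins over
  [-180, 180]^2^.
* **Region classification.** Rectangular boxes, declared constants:
  alpha_R Phi in [-100, -30], Psi in [-80, -5]; three10_R Phi in [-80, -40],
  Psi in [-45, -10] (tested first as a subset of alpha); beta Phi in
  [-180, -90], Psi in [90, 180]; PPII Phi in [-90, -20], Psi in [120, 180];
  left-handed helix boxes are point reflections of the right-handed ones.
  The literature names these regions without defining boundaries, so the
  boxes are package constants, not fitted quantities.
* **Hydrogen bonds.** A backbone bond in a frame is acceptor O(i) ... donor
  N(j) with heavy-atom distance <= 3.5 A and N-H...O angle >= 135 degrees;
  the amide H is reconstructed at 1.01 A along the bisector-opposed
  direction when absent. The distance default is 3.5 A rather than the 3.0 A
  sometimes used for relaxed MD ensembles because on ideal rigid-geometry
  helices (canonical angles, standard bond lengths) the alpha-helix
  N(i+4)...O(i) distance is 3.09 A -- a 3.0 A cutoff would classify an ideal
  alpha helix as unbonded. At 3.5 A the 135-degree angle criterion alone
  separates the turn classes: ideal alpha helices yield exclusively i+4 -> i
  bonds and ideal 3_10 helices exclusively i+3 -> i. Turn classes follow
  the separation j - i: 2 = gamma, 3 = 3_10, 4 = alpha, otherwise "other"
  (longer-range pairs are reported without interpretation).
* **RMSD and RoG.** RMSD-to-average centres all frames, superposes them
  onto their coordinate average with the optimal (Kabsch) rotation,
  recomputes the average once from the superposed frames, and reports each
  frame's RMSD to it, over backbone C, CA, N by default. The radius of
  gyration is the RMS distance of the selected atoms from their centroid
  (unit masses). Both are invariant under global rigid motion.

Numerically reproducing the published hydrogen-bond fractions or the
RMSD/RoG landscape of the reference trajectory is explicitly out of scope:
those depend on an undeposited 100 ns stochastic trajectory. The package's
claims are property-based instead, and every property is checked on
synthetic ensembles with known structure.

## Synthetic data: what it does and does not emulate

`simulate_peaklist()` is a forward model of the observable ion set: adduct
peaks, the b series minus a dropout set (default {b1, b13, b14}, mirroring
the characteristic missing fragments of this compound class), y~7~ and
optional MS^2^ sub-ions. m/z values get Gaussian noise (centroid jitter of
an ion trap; 0.05 Da in the round-trip conditions) and intensities are
log-uniform. It does **not** simulate isotope patterns, charge states above
2, chimeric spectra, adducts other than H^+^/Na^+^, or physically motivated
intensities -- so the round-trip results demonstrate correctness of the
assembly logic under realistic mass error and fragment dropout, not
robustness to every artefact of real spectra.

`generate_helix_ensemble()` builds backbones by internal-coordinate
chaining with standard geometry (N-CA 1.458, CA-C 1.525, C-N 1.329 A, ideal
angles, omega = 180) from canonical helix angles (alpha -57/-47, 3_10
-49/-26, mirrored for left-handed) plus Gaussian angle jitter. It produces
idealised, solvent-free backbones: adequate for validating dihedral,
classification, hydrogen-bond and superposition machinery, not a substitute
for molecular dynamics.

Both generators are bit-reproducible under a fixed seed and restore the
caller's RNG state.

## Problem sizes and determinism

The test suite round-trips all 30 packaged compounds at 0.05 Da noise,
checks the noise-monotonicity of recovery at sigma in {0, 0.05, 0.1, 0.3},
and uses ensembles of up to 500 frames x 8 residues for the histogram-mode
checks -- sizes chosen so the whole suite runs in well under a minute while
keeping every estimate far from its decision boundary. All pipeline stages
are deterministic given identical inputs and seeds; reports are
byte-identical across repeated runs.

## Known limitations

* Scaffolds other than 19-residue acetyl-capped amino-alcohol peptaibols
  are not assembled de novo (the chemistry functions handle any length the
  library covers).
* Isobaric discrimination (Leu/Ile, Val/Iva) is out of reach of the data
  this package models, and the output never pretends otherwise.
* The naming rule reproduces the primary published table; one pair in the
  second table is labelled against the ascending-y~7~ convention and is not
  reproduced.
* The packaged comparison database is a curated reconstruction from
  printed exchange records, not a copy of any external database; a handful
  of printed records are internally inconsistent and are documented in the
  fixture itself.
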