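---
title: "Methods: thermodynamic decomposition of protein-ligand binding"
author: "BindEntropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic decomposition of protein-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BindEntropy)
```

BindEntropy dissects the thermodynamics of a small protein domain binding a
series of closely related ligands — the motivating system is the galectin-3
carbohydrate recognition domain with fluorinated phenyltriazolyl
thiodigalactoside analogues — into overall binding thermodynamics (ITC),
per-residue conformational entropy (NMR order parameters), and
trajectory-derived entropies (dihedral histograms, iRED). This vignette
documents the models, the parameters that matter, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Overall binding thermodynamics from ITC

A single-site binding model links the total protein concentration $M_i$ and
ligand concentration $X_i$ in the cell after injection $i$ to the complex
concentration through the mass-action quadratic

$$[PL]_i = \tfrac{1}{2}\left(\alpha - \sqrt{\alpha^2 - 4 n M_i X_i}\right),
\qquad \alpha = n M_i + X_i + K_d,$$

where $n$ is the fraction of binding-competent protein. The cumulative heat
is $Q_i = V_0 \,\Delta H^\circ\, [PL]_i$ and the observed differential heat
corrects for the volume displaced by each injection,

$$q_i = Q_i - Q_{i-1} + \frac{V_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2} + Q_\mathrm{off},$$

with one heat offset $Q_\mathrm{off}$ per replicate absorbing heats of
mixing. Dilution bookkeeping uses the standard perfusion (overfill) model:
every injection displaces its own volume of well-mixed cell contents, so for
constant injection volume $v$, $X_i = X_0 (1 - v/V_0)^i$ and
$M_i = M_\mathrm{syr} [1 - (1 - v/V_0)^i]$. `fitGlobal()` fits all
replicates simultaneously with shared $(n, K_d, \Delta H^\circ)$ by
weighted Levenberg–Marquardt least squares on $\log K_d$; parameter
standard deviations come from the covariance of the fit scaled by the
reduced chi-square, reported symmetric. Derived quantities follow
$\Delta G^\circ = RT \ln K_d$ (standard state 1 M,
$R = 8.314\ \mathrm{J\,mol^{-1}\,K^{-1}}$) and
$-T\Delta S^\circ = \Delta G^\circ - \Delta H^\circ$.

**Reference titration conditions.** The experiments being emulated report
duplicate titrations at 301.1 K with roughly 2% heat noise and final
saturations of 97.6/97.0/92.4% for the three complexes at low-micromolar
$K_d$. A titration whose syringe species is ~10-fold more dilute than the
cell species can never approach saturation of the cell contents and leaves
$(n, K_d, \Delta H^\circ)$ unidentifiable; the reported saturations instead
pin the identifiable direction. `referenceScheme()` therefore titrates
20 × 2 µL of 1 mM titrant into a 250 µL cell at 100 µM (Wiseman
$c \approx 50$, final molar ratio ≈ 1.7), which reproduces ~97% final
saturation at $K_d = 2\ \mu\mathrm{M}$ and makes the global fit
well-conditioned. First-injection exclusion is available as a flag
(`excludeFirst`) and off by default. Saturation is also exposed as a plain
calculator, `saturation()`.

## Model-free analysis of NMR relaxation

Amide ¹⁵N relaxation ($R_1$, $R_2$, {¹H}–¹⁵N NOE at 11.7, 14.1 and 18.8 T)
and methyl ²H relaxation (the four coherences $R_1(D_z)$, $R(3D_z^2-2)$,
$R_2(D_+)$, $R(D_+D_z + D_zD_+)$ at 11.7 and 14.1 T) are interpreted with
the Lipari–Szabo model-free formalism. The spectral density for a bond
vector on a molecule tumbling with rotational diffusion tensor
$\{D_{XX} \le D_{YY} \le D_{ZZ}\}$ uses the Woessner multi-exponential
decomposition — one exponential for isotropic, three for axially symmetric,
five for rhombic tensors — with weights determined by the direction cosines
of the bond vector in the tensor frame (validated in development against a
Brownian-dynamics simulation of anisotropic rotational diffusion). Each
internal-motion component (amplitude $a_c$, correlation time $\tau_c^{int}$)
combines with each overall exponential through
$1/\tau_\mathrm{eff} = k_j + 1/\tau_c^{int}$.

Interaction constants: N–H bond length 1.02 Å, ¹⁵N CSA −172 ppm, and a ²H
quadrupolar coupling constant of 167 kHz (configurable through
`spinConstants()`; the 167 kHz default is the conventional methyl value).
Methyl spectral densities carry the $P_2(\cos 109.47^\circ)^2 = 1/9$
scaling of the axis order parameter from fast methyl rotation, whose
timescale is subsumed in $\tau_f$.

**Model ladder and selection.** Backbone sites fit
$\{O^2\}$, $\{O^2, \tau_e\}$, $\{O^2, R_{ex}\}$, $\{O^2, \tau_e, R_{ex}\}$;
methyl sites fit $\{O^2, \tau_f\}$, $\{O^2, \tau_f, \tau_s\}$ and the
extended $\{O_f^2, O_s^2, \tau_f, \tau_s\}$. A larger model is accepted
only when an F-test prefers it at $p < 0.05$; AIC is available as an
option. $R_{ex}$ is defined at the lowest field (11.7 T) and scales with
$B_0^2$, the standard fast-exchange convention. Parameter errors come from
Monte-Carlo refits of noise-resampled data (500 samples by default where
enabled). Fits use multi-start Nelder–Mead over scaled parameters (grid of
$O^2$, $\tau_e$, $R_{ex}$ starting points) to avoid the known local-minimum
trap of the $(O^2, \tau_e)$ surface; the one-parameter model uses Brent
minimization.

**Tensor fitting.** `fitDiffusionTensor()` alternates per-site local fits
(with model selection) and tensor optimization until the global chi-square
converges; whether the original analyses iterated or fitted jointly is
rarely documented, and alternating refinement converges here in a handful
of rounds. $\tau_c$ is initialized from the median $R_2/R_1$ ratio at the
highest field. Rigid-site preselection keeps sites with NOE > 0.65 at the
highest field. Axial and rhombic fits start the axis orientation from
several points on the sphere to avoid orientation minima. Anisotropy and
rhombicity are reported as $\zeta = 2 D_{ZZ}/(D_{XX}+D_{YY})$ and
$\eta = 1.5 (D_{YY}-D_{XX}) / [D_{ZZ} - (D_{XX}+D_{YY})/2]$, with
$\eta \equiv 0$ at the isotropic singularity.

## Conformational entropy from order parameters

Backbone entropy differences between two states A and B use the
diffusion-in-a-cone relationship per residue $k$:

$$\Delta S_\mathrm{bb} = R \sum_k
\ln \frac{3 - \sqrt{1 + 8\,O^2_{A,k}}}{3 - \sqrt{1 + 8\,O^2_{B,k}}},$$

reported as $-T\Delta S$ at 301 K. The form is antisymmetric in (A, B),
additive over residues, and finite for $O^2 < 1$; order parameters at or
above 1 (possible from fit noise) are clipped to $1 - 10^{-6}$ with a
warning naming the sites. Side-chain (methyl-axis) entropy uses the linear
per-residue-type relationship $\Delta S = -R\, C_m\, \Delta O^2$ with
$C_m = 1.32$ (Val, Thr), 3.1 (Ile, Leu) and 2.31 (Met); alanine, whose
methyl reports directly on the Cα–Cβ axis, is routed through the log-ratio
form. Because the three-complex design compares each complex with the mean
of the other two, `intercomplexDelta()` implements
$\Delta P(A) = P(A) - [P(B) + P(C)]/2$; the three deltas sum to zero and
equal 1.5 times the deviation from the three-way mean, and any pairwise
reference used to build per-complex sums cancels exactly. Monte-Carlo
errors resample every $O^2$ from its stated sd (clipped to $[0, 1)$).
Comparisons drop sites missing in any complex listwise, mirroring the
common-subset convention (116 backbone amides, 73 methyls in the
motivating data).

## Radial entropy shells

`residueLigandDistances()` takes the shortest distance between any ligand
atom and any atom of each residue (atoms as present in the file; no
hydrogens are added). Residues are sorted into shells of 1 Å width from
2–9 Å and 2 Å width from 9–27 Å, membership half-open $[\ell, u)$ so each
residue lands in exactly one shell. Shell means are referenced by
subtracting the minimum shell mean (the least-entropic shell defines 0);
the cumulative curve is the residue-weighted mean over all residues within
each shell midpoint, on the raw scale. Empty shells are recorded as
missing, never as zero; residues inside 2 Å (physically unexpected) join
the innermost shell with a warning.

## Trajectory entropies

Dihedral entropies are histogram entropies $S = -R \sum p \ln p$ over 5°
bins (72 per dihedral; 72 × 72 for backbone φ/ψ pairs), natural logarithm,
bin origin at −180° with ties to the upper bin. They are normalized to the
free rotor: $-T\Delta S = -T (S - R \ln 72^d)$ for dimensionality $d$, so
the uniform distribution scores exactly 0 and a single-bin distribution
scores $RT \ln 72 = 10.70$ kJ/mol at 301 K. The 2-D reference is the
product reference $R \ln 72^2$; treating φ and ψ jointly already captures
their mutual correlation, and correlations between different residues'
dihedrals are neglected (their effect on this system's entropies is
reported to be under 1 kJ/mol). Block averaging splits a series into 5 ns
windows of 500 snapshots at 10 ps sampling (100 ns → 20 blocks per
trajectory) and reports mean ± standard error over blocks; the per-block
estimate carries the usual finite-sampling (Miller–Madow-scale) upward
bias in $-T\Delta S$, which the block convention accepts in exchange for
suppressing rare-event drift.

iRED order parameters build the matrix
$M_{ij} = \langle P_2(\hat u_i \cdot \hat u_j)\rangle$ over sites,
eigendecompose, and compute $O^2_i = 1 - \sum_m \lambda_m |m_i|^2$ over all
but the five largest eigenmodes (overall reorientation). The estimator is
exactly rotation invariant. For finitely many sites, a fraction ≈ 5/N of
internal variance leaks into the five discarded modes, biasing $O^2$ up by
about $5(1-O^2)/N$; validation against the analytic cone model
$O^2 = [\cos\theta (1+\cos\theta)/2]^2$ therefore uses hundreds of sites.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded explicitly and records its ground truth. Defaults
mirror the study conditions: duplicate 20-injection titrations with 2% heat
noise; 116 backbone sites at three fields with 1.5% rate noise (NOE sd
0.0075) and Beta-shaped $O^2$ with mean 0.837; $\tau_c$ near 7 ns; methyl
tables at two fields; von Mises dihedral mixtures with analytic binned
entropies; cone-model bond vectors; toy complexes with residues at
prescribed ligand distances (axis-aligned placement keeps distances exact
at the 0.001 Å PDB precision).

The generators emulate noise and design, not physics beyond the fitted
models: relaxation data are generated from the same spectral-density family
that is fitted (no model mismatch), dihedral series are i.i.d. rather than
autocorrelated, cone vectors wobble independently between snapshots, and
toy complexes have no realistic covalent geometry. Passing recovery tests
therefore demonstrates correctness and identifiability of the estimators
under the stated noise, not robustness to model error in real spectra or
trajectories.

## Problem sizes and tolerances

Recovery studies run at the sizes of the motivating datasets: 100 seeded
duplicate titrations for the ITC study; one 116-site protein at three
fields and a 50-orientation axial protein for the tensor studies; 10⁵
snapshots for dihedral entropy checks; 200 sites × 600 snapshots for the
cone validation. Optimizer tolerances: Levenberg–Marquardt defaults for
ITC/decay fits, Nelder–Mead relative tolerance 10⁻¹² on chi-square for
model-free fits, alternating tensor refinement stops when the global
chi-square changes by < 10⁻⁶ relative. Degenerate inputs are handled
explicitly: constant decays are flagged rather than fitted, near-parallel
NH vector sets trigger an isotropic fallback with a warning, and empty
ligand selections or mismatched site sets raise errors naming the offender.

## Known limitations

- The ITC layer fits single-site binding only; competitive, multi-site and
  displacement formats are out of scope.
- Backbone model selection is restricted to the four basic model-free
  models; reduced spectral density mapping and relaxation dispersion are
  not implemented.
- Absolute conformational entropies (and the empirically calibrated
  whole-protein "entropy meter" scaling) are not computed; all entropy
  output is differences or profiles re-referenced within a complex.
- Trajectory ingestion is table-based (CSV of angles or unit vectors);
  binary MD trajectory formats are intentionally not parsed here.
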