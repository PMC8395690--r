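# BindEntropy

Thermodynamic decomposition of protein–ligand binding, built around
ligand binding to the galectin-3 carbohydrate recognition domain
(galectin-3C). Closely related ligands often bind with similar free
energies while hiding large, mutually compensating differences in
enthalpy, solvation, and conformational entropy. BindEntropy implements
the measurement-to-entropy pipeline that exposes those differences:

- **ITC**: single-site Wiseman isotherms with perfusion dilution
  bookkeeping, global fitting of replicate titrations with shared
  (n, K_d, ΔH°) and per-replicate heat offsets, and the derived
  thermodynamics ΔG° = RT ln K_d, −TΔS° = ΔG° − ΔH°.
- **NMR relaxation**: monoexponential decay fitting with jackknife or
  Monte-Carlo errors; Lipari–Szabo model-free analysis of ¹⁵N backbone
  (R₁, R₂, NOE at 11.7/14.1/18.8 T) and ²H methyl relaxation (four
  deuterium coherences), with isotropic/axial/rhombic rotational
  diffusion tensors (anisotropy ζ, rhombicity η), F-test model
  selection, and Monte-Carlo errors.
- **Conformational entropy**: per-residue backbone entropy from order
  parameters via the diffusion-in-a-cone log-ratio form, linear
  side-chain terms with residue-type coefficients (Val/Thr 1.32,
  Ile/Leu 3.1, Met 2.31; Ala through the backbone form), the
  three-complex comparison statistic ΔP(A) = P(A) − [P(B) + P(C)]/2,
  and Monte-Carlo error propagation.
- **Radial shells**: per-residue entropy profiles versus minimum
  residue–ligand distance (1 Å shells from 2–9 Å, 2 Å shells to 27 Å),
  referenced to the least-entropic shell.
- **Trajectory entropies**: dihedral-histogram entropies over 5° bins
  normalized to the free rotor, 5 ns block averaging, and iRED order
  parameters from bond-vector covariance eigenmodes.
- **Synthetic data**: seeded generators with recorded ground truth for
  every input (thermograms, rate tables, dihedral series, cone-model
  bond vectors, toy complexes), so the whole pipeline runs and is
  tested without any external downloads.

Chemical shift perturbations (weighted Euclidean, 0.16 for ¹⁵N / 0.25
for ¹³C) round out the measurement layer.

See the methods vignette
(`vignettes/binding-entropy-methods.Rmd`) for the models, assumptions,
numerical choices, and limitations.

## Worked example

Simulate a duplicate ITC experiment at the reference conditions
(20 × 2 µL of 1 mM titrant into 100 µM cell, 301.1 K, 2% heat noise),
fit it globally, and derive the thermodynamics:

```r
library(BindEntropy)

truth <- bindingParams(n = 1, Kd = 2.0e-6, dH = -50.4, Qoff = 0.3)
sim   <- genItc(truth, nReplicates = 2, noiseFrac = 0.02, seed = 7)
fit   <- fitGlobal(sim$thermograms)
fit
#> Global single-site ITC fit
#>   n    = 1.0133 +/- 0.0097
#>   Kd   = 1.9e-06 +/- 2.4e-07 M
#>   dH   = -49.11 +/- 1.34 kJ/mol
#>   Qoff = -0.145, -0.828
#>   chisq/dof = 1.073 (dof 35)

deriveThermodynamics(fit$params@Kd, fit$params@dH, temperature = 301.1,
                     KdSd = fit$sd["Kd"], dHSd = fit$sd["dH"])
#> ThermoSummary at 301.1 K: Kd = 1.9e-06 M
#>   dG   =  -32.98 +/- 0.32 kJ/mol
#>   dH   =  -49.11 +/- 1.34 kJ/mol
#>   -TdS =   16.12 +/- 1.38 kJ/mol
```

The fitted dissociation constant (1.9 ± 0.2 µM against a truth of
2.0 µM) gives ΔG° = −33.0 kJ/mol; the enthalpy and entropy split that
free energy into a favorable −49.1 kJ/mol enthalpic term opposed by a
+16.1 kJ/mol entropic penalty.

Conformational entropy differences between three complexes from
order-parameter tables (here synthetic 116-residue tables; `M`, `P`,
`O` label the complexes):

```r
set.seed(42)
O2   <- 0.6 + 0.38 * rbeta(116, 5, 3)                       # <O2> ~ 0.84
tabM <- orderParameterTable(1:116, rep("ALA", 116), pmin(O2, 0.98), sd = 0.012)
tabP <- orderParameterTable(1:116, rep("ALA", 116),
                            pmin(O2 + rnorm(116, 0, 0.01), 0.98), sd = 0.012)
tabO <- orderParameterTable(1:116, rep("ALA", 116),
                            pmin(O2 + 0.015, 0.98), sd = 0.012)

round(intercomplexEntropy(list(M = tabM, P = tabP, O = tabO), "backbone"), 2)
#>      M      P      O
#> -18.26 -17.85  36.11
round(entropyMcErrors(list(M = tabM, P = tabP, O = tabO), "backbone",
                      nMc = 500, seed = 1), 2)
#>    M    P    O
#> 5.19 6.11 7.73
```

The three −TΔΔS values (kJ/mol at 301 K) sum to zero by construction:
here the stiffer `O` tables carry a +36 kJ/mol entropic penalty relative
to the other two complexes, while `M` and `P` are equivalent within
their Monte-Carlo errors.

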