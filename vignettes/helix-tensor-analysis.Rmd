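---
title: "Shift-tensor analysis of helical membrane peptides with helixnmr"
author: "helixnmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-tensor analysis of helical membrane peptides with helixnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixnmr)
```

## The problem

Oriented-sample solid-state NMR determines how a helical peptide such as
the peptaibol alamethicin sits in a lipid bilayer: the helix tilt
$\tau$ (angle between helix axis and membrane normal $\vec n$) and the
azimuthal rotation $\rho$ of each residue about the axis. The
observables are anisotropic chemical-shift components, and their
interpretation requires the full chemical-shift tensor (CST) of each
backbone site — its principal values $\delta_{11}\le\delta_{22}\le
\delta_{33}$ and the orientation of its principal axes in the molecular
frame. Periodic DFT (GIPAW) calculations on a crystalline model of the
peptide supply site-specific *shielding* tensors $\sigma$; `helixnmr`
implements everything downstream of that calculation:

1. conversion of shielding principal values to *theoretical chemical
   shifts* $\varepsilon$ via a linear calibration;
2. the orientation angles $\alpha,\beta,\gamma$ of each tensor relative
   to its peptide plane;
3. backbone characterization (Ramachandran angles, hydrogen bonds) and
   helix parametrization (axis, radius, per-residue $\rho$, tilt
   $\tau$);
4. forward and inverse models of the oriented-sample observables; and
5. a synthetic-data generator that replaces the non-distributed DFT
   outputs with fully known ground truth.

## Shielding-to-shift calibration

The calibration is a negative-slope line
$\varepsilon_{pp} = a\,\sigma_{qq} + b$ applied element-wise to matched
principal values (largest shielding ↔ smallest shift). Two lines are
built in, parametrized against single-crystal CST measurements of small
peptides: for backbone amide ¹⁵N, $a = -0.93574$, $b = 209.54$ ppm; for
carbonyl ¹³C, $a = -0.99314$, $b = 172.50$ ppm (residual sd 1.8 ppm,
adjusted $R^2$ 0.99918). `fit_calibration()` reproduces such lines from
user-supplied $(\sigma, \delta)$ pairs by ordinary least squares; the
underlying glycylglycine-salt dataset of the ¹³C line is not
redistributed, so the printed coefficients ship as constants and the
fitting routine is validated on synthetic data.

```{r calibration}
shift_calibration("13C")
shielding_to_shift(c(155, 140, 20), shift_calibration("15N"))
```

Descriptors follow the field's conventions: the isotropic value is the
principal-value mean; the carbonyl "axial" anisotropy is
$\delta_{\mathrm{aniso}} = \delta_{22} - (\delta_{11}+\delta_{33})/2$
(the $\delta_{22}$ axis is taken along the helix); `haeberlen_order()`
ranks principal values by deviation from the isotropic value.

## Tensor orientation in the peptide plane

For an amide nitrogen the peptide plane $P_N$ is defined by
$\{N, H, C_\alpha\}$; for a carbonyl carbon, $P_C$ by
$\{C', O', C_\alpha\}$. With eigenvectors $\xi_1,\xi_2,\xi_3$ attached
to $\sigma_{11}\ge\sigma_{22}\ge\sigma_{33}$:

* ¹⁵N: $\alpha$ = out-of-plane elevation of $\xi_3$, $\beta$ =
  $\angle(\xi_3, N\!-\!H)$, $\gamma$ = $\angle(\xi_2, \hat n_{P})$;
* ¹³C: the same roles shifted one index down ($\xi_2$ elevated and
  compared with $C'\!=\!O'$, $\xi_1$ against the normal).

"Projecting onto the plane" is implemented as the out-of-plane
elevation, i.e. $90°$ minus the angle to the plane normal, which makes
$\alpha$ a direct measure of the departure of the relevant principal
axis from the plane. Eigenvectors are axes, not arrows, so every angle
is folded to the acute range $[0°, 90°]$ — consistent with reference
tables in which no orientation angle exceeds $70°$. Eigenframes whose
principal-value gap is below $10^{-6}$ ppm are flagged degenerate and
refused by the orientation routines, because their eigenvector
directions are numerically meaningless.

## Helix parametrization

The helix axis is obtained by a least-squares cylinder fit to the
ordered $C_\alpha$ positions: the direction minimizing the spread of
point-to-axis distances, initialized from the singular directions of
the centered point cloud and refined by Nelder–Mead, with the in-plane
circle center solved in closed form (Kasa fit) at each candidate
direction. This is a deliberate, documented design choice: the
validation surface is recovery of known generator geometry (axis to
0.1°, radius to 0.02 Å on ideal helices), not bit-agreement with any
particular published parametrization whose details are unavailable.
Candidate directions whose projection collapses the points onto a line
are rejected, which also resolves the flat limit (coplanar points on a
circle yield the circle normal).

Azimuths $\rho$ are measured per residue as the right-handed angle,
about the axis, between the axis-perpendicular component of the
residue's site vector and that of a reference residue ($\rho = 0$
there). The default site vector is the carbonyl bond $C'\!\to\!O'$,
the orientation that drives the ¹³C anisotropy oscillation; $C_\alpha
\!\to\!C'$ is available by flag. The reference-residue convention is
the package's own (first residue with a defined site vector unless
specified); published figures leave the $\rho = 0$ convention
unstated, so only *increments* (≈100°/residue on an ideal α-helix) are
meaningful for comparison, and $\rho$ is reported modulo 360°.

Hydrogen bonds are assigned per amide donor as the closest H···O
contact with H···O ≤ 2.5 Å and N–H···O ≥ 120° (configurable; typical
solid-state-structure practice — the defaults are stated here because
reference tables rarely print their criteria). Spans are reported from
the acceptor's perspective, so an α-helical bond is $i \to i{+}4$ and a
3₁₀ bond $i \to i{+}3$. When hydrogens are absent (XRD-derived files),
amide H is reconstructed in the $C'(i{-}1)$–N–$C_\alpha$ plane, 1.01 Å
from N along the external bisector.

## Oriented-sample observables

With the sample normal along the field, the measured parallel component
of an amide ¹⁵N CST follows

$$\delta_\parallel(\tau) = \delta_{11}\sin^2\tau + \delta_{33}\cos^2\tau,$$

the axially averaged specialization in which the $\delta_{33}$
direction is parallel to the helix axis (the general two-angle
expression reduces to this with the first Euler angle set to zero and
the second to $\tau$). `invert_tilt()` returns the principal branch
$\tau\in[0°,90°]$; the oriented-sample degeneracy $\tau \leftrightarrow
180°-\tau$ is documented rather than enumerated. Values of
$\delta_\parallel$ outside $[\min(\delta_{11},\delta_{33}),
\max(\delta_{11},\delta_{33})]$ are unreachable for any tilt and raise
a domain error naming the violated bound — see the worked example
below for why this matters in practice.

For carbonyl carbons the total anisotropy
$\Delta\delta = \delta_\parallel - \delta_\perp$ oscillates with the
residue azimuth:

$$\Delta\delta(\rho,\tau) = \tfrac{3}{2}\sin^2\tau\,
(\delta_{11}\cos^2\rho + \delta_{33}\sin^2\rho - \delta_{22})
+ \delta_{22} - \tfrac{\delta_{11}+\delta_{33}}{2},$$

valid under the assumption that the $\delta_{22}$ axis lies along the
helix (it is nearly collinear with $C'\!=\!O'$, as the small ¹³C
$\beta$ angles confirm). At $\tau = 0$ the oscillation vanishes and
$\Delta\delta$ reduces to the axial anisotropy; the $\rho$-average is
$\delta_{\mathrm{aniso}}(1 - \tfrac32\sin^2\tau)$, zero at
$\sin^2\tau = 2/3$. `scan_oscillation()` overlays a continuous curve
(computed from the segment-average principal values — the published
figure style draws one guide curve through site-specific points) with
one point per site from its own principal values at its own $\rho$.

### Worked tilt extraction

```{r tilt}
refs <- reference_shift_sets()
cons <- refs[refs$set == "aib_consensus", ]
dp <- delta_parallel(cons$d11, cons$d33, cons$tau_ref)
dp
n15 <- alm_shift_table("15N")
aib5 <- n15[n15$residue == "Aib5", ]
aib8 <- n15[n15$residue == "Aib8", ]
round(invert_tilt(dp, aib5$eps11, aib5$eps33), 1)
round(invert_tilt(dp, aib8$eps11, aib8$eps33), 1)
```

The consensus Aib principal values $\{64.5, 85.5, 232.5\}$ ppm at the
reference tilt $8.0°$ give $\delta_\parallel = 229.2$ ppm. Re-inverting
with the site-specific Aib5 and Aib8 tensors yields $5.0°$ and
$11.9°$: the site-to-site CST variation alone moves the extracted tilt
by several degrees. A parallel-shift value of $292.2$ ppm is sometimes
quoted for these inputs; it exceeds $\delta_{33} = 232.5$ ppm and is
therefore unreachable for any tilt — `invert_tilt()` rejects it, and
the recomputed $229.2$ ppm (consistent with a digit transposition) is
the value that reproduces both downstream tilts.

## Reference tables and group statistics

The calibrated per-residue tensor tables for the crystalline
alamethicin E18 model ship as plain CSV
(`alm_shift_table("15N")`/`("13C")`). Summary statistics split Aib from
proteinogenic residues; prolines (no amide plane) and the phenylalaninol
terminus are excluded from both groups. Quoted "±" spreads are sample
(n−1) standard deviations — that convention, not the population sd,
reproduces the reference spread of the eight Aib β values (1.3°, not
1.2°).

```{r stats}
tab <- alm_shift_table("15N")
cls <- classify_labels(tab$residue)
keep <- cls %in% c("Aib", "proteinogenic")
group_stats(tab$eps_iso[keep], cls[keep])[c("group", "n", "mean", "sd")]
```

One 1-decimal wrinkle is logged rather than hidden: averaging the
rounded proteinogenic $\varepsilon_{11}$ column gives 52.3 ppm where
52.4 ppm is sometimes quoted; `emit_report()` writes the recomputed
value and records group means in its run log so the discrepancy is
visible.

## The synthetic-data generator

`build_helix()` constructs backbone coordinates (N, H, C$_\alpha$, C',
O', plus a C$_\beta$ stub) from internal coordinates — standard bond
lengths (N–C$_\alpha$ 1.458 Å, C$_\alpha$–C' 1.525 Å, C'–N 1.329 Å)
and trigonal/tetrahedral angles — so the requested $\varphi/\psi$ are
realized exactly. The defaults, $\varphi = -57°$, $\psi = -47°$ and the
20-residue alamethicin E18 sequence with an acetyl cap, give an ideal
right-handed α-helix with ≈1.5 Å rise, ≈2.3 Å C$_\alpha$ radius and
≈100°/residue twist. Prolines are built without the amide H and the
phenylalaninol terminus without a carbonyl, mirroring the real residue
chemistry. Optional Gaussian coordinate noise is seeded and
reproducible.

`plant_tensors()` inverts the orientation-angle definitions: it builds
an eigenframe realizing prescribed $(\alpha,\beta,\gamma)$ exactly —
the elevated eigenvector placed at elevation $\alpha$ and bond angle
$\beta$, then the normal-referenced eigenvector at $\gamma$ within the
perpendicular subspace — and assembles $V\,\mathrm{diag}(\sigma)\,V^T$.
This construction requires $\beta \ge \alpha$ and $\gamma \ge \alpha$
(otherwise no orthonormal frame exists; the generator raises an error),
a constraint every reference-table row satisfies. Planted angles are
recovered to $10^{-6}$ degrees at zero noise; with tensor noise the
recovered angles are unbiased and converge as the noise vanishes.

What the generator does *not* emulate: side-chain rotamers, the broken
helix at Gly11 and the C-terminal 3₁₀ tendency of the real crystal
structure, crystal packing, and solvent. Passing tests on generator
output therefore validate the *algorithms* (angle definitions,
inversions, fits) — they do not certify accuracy of any DFT input.

## Numerical choices

* Angles are degrees at every interface, radians internally.
* Eigenvector signs: largest-magnitude component positive for
  $\xi_1,\xi_2$, then $\xi_3 = \xi_1\times\xi_2$ (right-handed);
  downstream angles are fold-invariant, so the convention only
  stabilizes printed vectors.
* Degeneracy threshold $10^{-6}$ ppm; plane-orthogonality tolerance
  $10^{-8}$.
* Report rounding: 1 decimal ppm / degree, half-up, matching printed
  reference tables; undefined cells render as an em dash.
* Table layouts print the signed sum $\varphi+\psi$: the reference
  "|φ+ψ|" column carries negative values, so the absolute-value bars
  are treated as typographical.
* PDB coordinates carry 3 decimals; angle closure through a PDB
  round-trip is good to ≈0.05°, while mmCIF output uses full precision
  (17 significant digits) and round-trips exactly.
* Problem sizes in the test-suite simulations (12-residue helices, 40
  noise replicates) keep the full suite in a few seconds while leaving
  Monte-Carlo error well below the asserted tolerances.

## Known limitations

* The cylinder-fit axis and the reference-residue $\rho = 0$ convention
  are package choices; compare azimuth *increments*, not absolute
  $\rho$, against other parametrizations.
* `invert_tilt()` ignores orientational distributions and dynamics: it
  maps one value to one principal-branch angle.
* No powder-pattern/MAS line-shape simulation, no $\delta_\perp$
  orientational formula, no span/skew conventions, no DSSP-style helix
  classification (the backbone table exposes $\varphi/\psi$ and
  hydrogen-bond spans for inspection instead).
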