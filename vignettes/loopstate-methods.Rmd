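---
title: "Methods: loop conformational coordinates, free-energy profiles, and ionic-strength analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop conformational coordinates, free-energy profiles, and ionic-strength analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstate)
```

## The problem

The M20 loop (residues 9–24) of *Escherichia coli* dihydrofolate reductase
closes over the active site during catalysis and is seen in crystal
structures in three canonical states — *open*, *closed*, and *occluded* —
depending on whether the loop "nose" (E17/N18) sits over the coenzyme
site, away from it, or over the substrate site. Crystallization buffers
for this enzyme frequently contain 2:1 salts (typically CaCl~2~) at
concentrations whose molar ionic strength,

$$I^M = \tfrac{1}{2}\sum_i c_i Z_i^2,$$

often exceeds the *E. coli* intracellular ceiling of roughly 0.24 M.
`loopstate` provides the quantitative machinery to ask whether the ionic
strength of the solution environment correlates with, and energetically
biases, the loop conformation: a scalar conformational coordinate over
loop/anchor geometry, free-energy profiles along that coordinate,
electrostatic potential profiles around the loop, solution-composition
utilities, and a survey stage over tables of PDB entries.

## The conformational coordinate

Two anchor points summarize the binding sites: $P_1$, the C^α^ centroid of
R44, H45, G97 and R98 on the coenzyme-binding helices C and F, and $P_2$,
the C^α^ centroid of ^28^LAWF^31^ on the substrate-binding helix B. The
loop itself is summarized by the turn point $j$ (C^α^ centroid of E17 and
N18) and by the side-chain heavy-atom centers of the tracked residues
E17, N18, M20 and P21 (backbone N, C^α^, C, O and OXT excluded; for
proline the ring carbons CB/CG/CD count as side chain).

For each loop point $p$ the signed anchor preference
$d_{P_2 \to p} - d_{P_1 \to p}$ is positive when $p$ lies nearer the
coenzyme anchor. The coordinate is the mean preference over the five loop
points,

$$R_c = \frac{1}{5}\left[\bigl(d_{P_2\to j} - d_{P_1\to j}\bigr)
  + \sum_{i} \bigl(d_{P_2\to i} - d_{P_1\to i}\bigr)\right],$$

so *closed* loops (nose over the coenzyme site) score high, around
5.8–7.4 Å, *occluded* loops (nose toward the substrate site) score low
(below 2 Å, and negative when the nose crosses toward helix B), and
*open* loops fall between, around 4.6–5.7 Å. $R_c$ is built purely from
distances, hence exactly invariant under rigid-body motion, and the test
suite asserts this to 10^-9^ Å.

Two design points were genuinely open and resolved as follows:

* **Disordered side chains.** A tracked residue with no side-chain heavy
  atoms in the model (as for E17–M20 in PDB 1rg7) is dropped from the sum
  with a warning and the mean runs over the remaining points. This keeps
  the coordinate defined for partially disordered loops instead of
  failing.
* **Class boundaries.** The crystallographic ranges leave gaps
  (occluded < 2, open 4.6–5.7, closed 5.8–7.4 Å). Defaults close the
  open/closed gap at its midpoint 5.75 Å, label 2.0–4.0 Å
  "intermediate", and start "open" at 4.0 Å; all boundaries are a single
  argument (`class_boundaries()`) so the narrower printed ranges can be
  used instead.

The two marker distances C^α^(N18)–C^α^(H45) (≈7 Å closed vs ≈11–13 Å
open) and C^α^(E17)–C^α^(L28) (short in occluded structures) are reported
alongside the coordinate, and the reaction plane through the three
C^α^-group centroids on helices B, C and F is available for geometric
context (`reaction_plane()`).

## Free-energy profiles

With $\rho\langle R_c\rangle$ the probability density of $R_c$ collected
from trajectories, the potential of mean force is

$$W(R_c) = -RT \ln \rho\langle R_c\rangle,$$

with $R = 1.9872 \times 10^{-3}$ kcal/(mol·K) and $T = 298.16$ K by
default, referenced so the sampled minimum is zero. Numerical choices:

* **Bin width 0.2 Å** by default, matching the umbrella-window spacing;
  the default range $[-4, 9]$ Å spans the profiles the coordinate
  produces for this loop.
* **Empty bins are masked**, never padded with pseudo-counts, so the
  logarithm of zero is never taken.
* **Pooling** of several simulations of identical composition sums bin
  counts before normalization; this is algebraically identical to
  inverting the concatenated samples, and the tests assert exact
  equality.
* **Umbrella bias.** The printed force-constant unit for umbrella
  potentials ("10 kcal/mol/Å at 0.2 Å intervals") is interpreted as a
  harmonic constant $k$ in kcal/(mol·Å²) with the
  $\tfrac12 k (x-x_0)^2$ convention; `convention = "full"` switches to
  $k(x-x_0)^2$ for cross-checks against tools that fold the ½ into $k$.
* **WHAM.** `wham_join()` solves the standard self-consistent equations
  over a shared grid, iterating the unbiased density and the per-window
  constants until the constants move by less than `tol` (default
  10^-7^ kcal/mol, capped at 10^5^ iterations, with iteration count and
  residual attached to the result). Windows must form a connected chain
  of overlapping sampled support; disconnected windows are an error, not
  a silent extrapolation. With all force constants zero the estimator
  reduces exactly to pooled Boltzmann inversion, which the tests assert
  to 10^-9^.
* **Barriers** are reported as the crossing cost from the *shallower*
  well: the maximum of $W$ on the sampled span between the two well
  minima minus the higher minimum. This matches the natural reading of a
  barrier "to reach one state from the other".
* **Error bars** use contiguous block averaging with 3 blocks by default,
  mirroring three independent simulations; each block is inverted
  separately on the common grid and the per-bin standard error across
  blocks is reported.

## Electrostatic potentials at the loop

The reference point is the geometric center of the C^α^ atoms of E17, N18
and M20, carrying charge $q^\alpha = -1$ e (the deprotonated E17
carboxylate). The distance-dependent ion potential is computed by
particle summation,

$$\Phi^\alpha(R)^{\mathrm{ion}} = \Bigl\langle \sum_{r_i \le R}
  \frac{k_C\, q_i}{r_i} \Bigr\rangle_{\text{frames}},$$

with $k_C = 332.0637$ kcal·Å/(mol·e²), minimum-image distances in the
cubic box, vacuum screening (no dielectric constant — the solvent is
explicit), and no Ewald images. The same operation applied to water atoms
with TIP3P partial charges (O $-0.834$ e, H $+0.417$ e) gives
$\Phi^\alpha(R)^{\mathrm{solv}}$. An independent route integrates the
radial distribution function,

$$\Phi^\alpha(R) = \sum_X 4\pi \rho_X q_X k_C \int_0^R r\, g_{\alpha-X}(r)\,dr,$$

and the two routes are required to agree on identical frames; this
dual-route contract *is* the definition the package is tested against.
Practical guards: frames with a particle inside 0.5 Å of the reference
are rejected with a warning (a single near-contact otherwise dominates
the average), a particle exactly at the reference is an error, and
$R_{\max}$ may not exceed half the box edge. The innermost shells hold
$O(1)$ ions, so comparisons between the two routes are made from
$R \approx 2$ Å outward where both estimators are statistically
meaningful.

The linear-response free-energy estimate is
$\Delta G \approx \tfrac12 q^\alpha \Phi^{\mathrm{total}}(R_{\text{large}})$
with $R_{\text{large}} = 20$ Å as the conventional evaluation radius.
The protein contribution to $\Phi^{\mathrm{total}}$ requires per-atom
force-field charges and is accepted as a supplied number rather than
computed; `lfer_free_energy()` is therefore arithmetic on totals by
design.

## Solution composition utilities

`ion_counts_for_box()` converts a concentration to integer counts via
$N = \mathrm{round}(c N_A V)$ (round-half-to-even) for the cation and
restores salt stoichiometry through exact charge balance on the anion;
for 0.025 M CaCl~2~ in the 93 Å box this gives 12 Ca²⁺ and 24 Cl⁻.
`neutralize_counts()` then enforces overall neutrality around a charged
solute using the minimal number of monovalent counterions, adjusting
anions first. `place_ions()` inserts ions sequentially at random
positions subject to a 15 Å anti-clustering spacing and a solvent
overlap cutoff; because the source description of the 15 Å rule is
ambiguous about whether it applies to the last-placed ion or to all
previous ions, both modes exist and the stricter all-pairs mode is the
default (it is the one that actually prevents clustering). Placement
retries up to 10,000 times per ion before raising an indexed error.
`trim_waters()` removes whole water molecules with any atom inside 2.8 Å
of a protein heavy atom.

## The survey stage

`parse_survey_table()` ingests a tab-separated table of PDB entries with
their crystallization salt and concentration;
`annotate_ionic_strength()` fills $I^M$ through the same species
arithmetic as the solution module (a fixed vocabulary of NaCl, KCl,
CaCl~2~, MgCl~2~, MnCl~2~ — the surveyed structures were solved in 1:1 or
2:1 chloride salts, so a general formula parser would be unexercised
surface area); `attach_rc()` computes $R_c$ for records whose structure
file is available; and `summarize_survey()` splits conformer counts at
the physiological threshold, 0.24 M by default with 0.25 M one argument
away. Records missing either $I^M$ or a class are excluded and counted,
so classified + excluded always equals the table size.

## Synthetic ground truth

The generators exist so that every analysis stage has an exact oracle:

* `sample_rc()` draws i.i.d. samples from $\exp(-W/RT)$ by inverse-CDF
  lookup on a 10^-3^ Å grid — exact Boltzmann statistics with no
  autocorrelation.
* `double_well()` builds a C¹ two-state potential with *exactly*
  controlled well positions, depth offset and barrier (raised-cosine
  interior, harmonic walls). Defaults place the wells at $R_c = -0.17$
  and 6.0 Å — the occluded and closed minima of the high-ionic-strength
  profiles — with a 0.5 kcal/mol depth offset (comparable-depth wells,
  slightly favoring the deeper state, a realistic two-state free-energy
  offset of order $RT$) and barrier settings of 1.6 or 3.2 kcal/mol,
  the low- and high-ionic-strength barrier values used as generator
  conditions.
* `toy_anchor_layout()` + `embed_frames()` realize samples as 3-D frames:
  anchors at fixed positions 15 Å apart and the loop points riding a
  straight offset path whose map $t \to R_c$ is precomputed, verified
  strictly monotone, and inverted by interpolation. The embedding
  round-trips through `rc_timeseries()` to within 0.01 Å. Only the atoms
  entering the coordinate are emitted; the generator tests the
  coordinate's arithmetic, not sterics.
* `gen_umbrella_samples()` runs Metropolis chains on $W$ + bias, adapting
  the step during the discarded 10% burn-in toward a 30–50% acceptance
  rate and thinning by 5.
* `gen_ionic_config()` emits ideal-solution frames (Poisson counts,
  uniform positions, optional hard core) that exactly satisfy the
  uniform-fluid assumptions of the RDF and potential oracles.

All generators are seed-deterministic and record their provenance
(seed, sizes, acceptance rates).

**What passing tests do and do not show.** The synthetic trajectories
have exact Boltzmann statistics, no time correlation, no water structure,
no ion–protein specific interactions, and loop geometry confined to a
one-parameter path. Recovery of generator ground truth therefore
validates the estimators (binning, inversion, WHAM joining, barrier
measurement, potential summation) — it does not reproduce, and cannot
stand in for, microsecond explicit-solvent molecular dynamics of the
solvated enzyme. Profiles from real trajectories additionally face
sampling and equilibration questions that are out of scope here.

## Problem sizes and runtime choices

The verification suite uses 10^6^ inverse-CDF samples for the Boltzmann
round trip and the end-to-end barrier recoveries (statistical error in
well-sampled bins ≈ 0.03 kcal/mol, comfortably inside the asserted
0.1–0.15 kcal/mol bounds), 48 umbrella windows × 1500 Metropolis samples
for the WHAM recovery, and ~10^5^ particle·frames for the electrostatic
dual-route comparison. These sizes were chosen so each stage's assertion
sits well above its sampling noise floor.

## Known limitations

* The trajectory readers cover the plain-text frame dialect, multi-MODEL
  PDB, and DCD (through bio3d); XTC is not supported.
* The cumulative potentials use minimum-image distances only; there is no
  Ewald/PME treatment, consistent with the particle-summation definition.
* The survey's salt vocabulary is fixed; buffer components other than the
  named salt (PEG, Tris, ...) do not contribute to $I^M$.
* `fetch_pdb()` is the only network-touching function and is never called
  by the core analysis path.
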