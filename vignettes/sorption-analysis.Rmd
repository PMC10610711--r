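---
title: "Methods: penetrant sorption analysis in periodic MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penetrant sorption analysis in periodic MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sorbtrack analyses the transport of a penetrant — typically water — through a
polymer matrix as recorded by molecular dynamics trajectories under
orthorhombic periodic boundary conditions. This vignette is the package's
account of the methods themselves: the models, the parameters that matter,
the numerical choices, and what the built-in synthetic generators do and do
not establish about real trajectories.

## Self-diffusion from the mean-squared displacement

The central quantity is the multi-origin mean-squared displacement of the
penetrant molecules' centres of mass,

$$\mathrm{MSD}(\tau) \;=\; \big\langle\, \lvert \mathbf{r}_i(t_0+\tau) -
\mathbf{r}_i(t_0) \rvert^2 \,\big\rangle_{i,\,t_0},$$

averaged over molecules $i$ and time origins $t_0$. For Fickian diffusion in
three dimensions the Einstein relation gives the self-diffusion coefficient
as one sixth of the long-time slope,

$$D \;=\; \frac{1}{6}\,\lim_{\tau\to\infty}\frac{d\,\mathrm{MSD}(\tau)}{d\tau}.$$

With coordinates in Å and times in ps, the unit conversion is
$1\ \text{Å}^2/\text{ps} = 10^{-8}\ \text{m}^2/\text{s}$.

Design choices, each genuinely open in the literature, resolved as follows:

* **Centres of mass, not atoms.** Self-diffusion of a molecular penetrant is
  a molecular property; using the centre of mass removes libration and
  rotation noise from the short-lag MSD. `compute_msd()` therefore groups
  the selection by molecule and weighs atoms by mass.
* **Origin averaging.** A single-origin MSD (each particle against its
  $t=0$ position) is an unbiased but very noisy estimator. Smooth MSD
  profiles require averaging over origins, so the default uses every frame
  as an origin (`origin_stride = 1`); the stride is exposed for users who
  want cheaper, less correlated sampling.
* **Unwrapped coordinates.** Wrapped coordinates fold displacements back
  into the box and make the MSD saturate at the box scale. `unwrap()`
  reconstructs continuous paths by accumulating minimum-image frame-to-frame
  steps; this is exact whenever no molecule travels half a box edge between
  recorded frames, and a step that reaches $L/2$ raises an explicit
  ambiguity warning naming the atom and frame.
* **Fit with intercept.** The Einstein fit is ordinary least squares of MSD
  against lag *with* an intercept, which absorbs the short-time
  ballistic/cage offset instead of biasing the slope.
* **Default lag range.** `compute_msd()` caps lags at 10% of the trajectory
  span: the number of independent origin pairs falls as the lag grows, and
  beyond roughly a tenth of the run the estimator is statistically starved.

### Identifying the Fickian window

Before an Einstein fit is meaningful, the linear regime must be identified:
sub-diffusive (confined) transport shows a double-logarithmic slope below 1,
ballistic motion a slope of 2. `loglog_slope()` computes a moving-window
least-squares slope of $\log_{10}\mathrm{MSD}$ versus $\log_{10}\tau$
(half-width `half_window = 3` points by default, truncated at the ends), and
`detect_linear_window()` returns the longest contiguous lag interval whose
local slopes all lie in `slope_band` (default $[0.9, 1.1]$) and which spans
at least `min_span = 0.5` decades of lag. Ties are broken in favour of the
earliest interval so results are deterministic. When no interval qualifies —
as on purely ballistic or fully confined input — the function refuses with
an instruction to supply a window manually rather than fitting a
non-diffusive regime silently.

### Uncertainty

Published diffusion tables quote uncertainties without defining the
estimator, so the package makes its own explicit: `block_stderr()` splits
the molecules into `n_blocks = 5` disjoint groups (deterministic round-robin
assignment), refits $D$ per block over the same window, and reports the
standard error of the block mean. This measures molecule-to-molecule
sampling error and is appropriate when penetrant paths are approximately
independent; it does not capture systematic error from window choice.

## Geometric hydrogen-bond census

A hydrogen bond D–H···A is accepted when three geometric criteria hold
simultaneously:

* H···A minimum-image distance **strictly less than** `max_ha` (default
  2.8 Å);
* donor angle ∠(D–H···A), measured at the hydrogen, **at least**
  `min_donor_angle` (default 120°, inclusive);
* acceptor angle ∠(H···A–X) **at least** `min_acceptor_angle` (default 90°,
  inclusive) for **every** heavy neighbour X bonded to the acceptor. An
  acceptor with no heavy neighbour — a water oxygen, or a bare ion — passes
  this test vacuously.

Donors are N/O atoms with bonded hydrogens (the hydrogens carry the
`donor_h` flag); acceptors are flagged N/O atoms. Placing the donor angle at
the hydrogen and testing the acceptor against all of its heavy neighbours is
the convention of the Maestro-style geometric definition; it is conservative
and fully deterministic. Intramolecular pairs are excluded for water (a
rigid three-site molecule cannot hydrogen-bond to itself) but allowed for
polymer molecules when donor and acceptor are more than three covalent bonds
apart, since crosslinked chains legitimately self-bond.

Bonds are classified by the species of the donor and acceptor *molecules*:
water–water (`ww`), polymer–polymer (`pp`), and polymer–water (`pw`), with
filler counted as polymer. The counts satisfy the exact identity
$N_{T} = N_{ww} + N_{pp} + N_{pw}$, and `pw_by_difference()` implements the
complementary decomposition $N_{pw} = N_{T} - N_{pp} - N_{ww}$ used when a
toolchain reports only totals and like-species counts. The test suite holds
this identity integer-exactly on every input; note that published tables
that round time-averaged means per class can appear off by one in the
difference, and the implementation deliberately does not "repair" such
inputs.

### Boundary behaviour

Threshold comparisons carry a guard band of $10^{-9}$ (Å or degrees): a
geometry constructed *exactly* on a boundary evaluates with rounding error
of order $10^{-13}$, and the guard makes the strict-distance /
inclusive-angle semantics hold regardless of the rounding direction.
Geometries more than $10^{-9}$ from a threshold are unaffected. Without the
guard, whether "exactly 120°" passes would depend on floating-point
round-off in the scene's coordinates.

## Water clustering under periodic boundaries

Water molecules are partitioned by single-linkage clustering: molecules are
linked when their minimum-image oxygen–oxygen distance is at most `cutoff`,
and clusters are the connected components (union–find). Single linkage is
the natural formalisation of clusters that "break and re-form" by gaining
and losing contacts, and it admits an exact brute-force oracle, which the
suite exercises up to 200 molecules.

Two choices are not dictated by any published protocol and are therefore
config-exposed with defaults:

* **Linkage distance O–O, cutoff 3.5 Å** — the first minimum of the bulk
  water oxygen–oxygen pair correlation function, the standard definition of
  a first-shell contact.
* **Per-frame identity only.** Cluster statistics (largest size, count,
  radius of gyration) are reported per frame; no attempt is made to track
  cluster lineage across frames.

The mass-weighted radius of gyration
$R_g = \sqrt{\sum_i m_i \lvert \mathbf{r}_i - \mathbf{r}_{cm}\rvert^2 / \sum_i m_i}$
is computed over all atoms of the member molecules after making the cluster
whole: a breadth-first traversal of the linkage graph places each molecule
next to its already-placed neighbour via minimum-image shifts, so
boundary-spanning clusters are measured un-split. A cluster whose unwrapped
extent reaches half a box edge is periodically ambiguous (it may percolate)
and triggers a warning. Output ordering is deterministic: descending size,
ties broken by smallest member molecule id.

## Density projection

`project_density()` bins molecular centres of mass on one or two box axes,
integrating the remaining axes out, and averages over frames. Values are
densities (count or mass per Å or Å²) normalised so that
$\sum \text{values} \times \text{bin measure}$ equals the mean selected
count (or mass) per frame — an identity the tests hold exactly. The
requested bin width (default 1 Å) is rounded to the nearest integer divisor
of the box edge so that bins tile the box exactly and refining by an integer
factor re-aggregates to the coarse map without remainder. Molecules
straddling the boundary are made whole by minimum-image anchoring before
their centre of mass is computed, then the centre is wrapped back into the
box.

The summary statistic `uniformity_cv()` is the population coefficient of
variation of the bin values: 0 for a perfectly even distribution, rising as
the penetrant concentrates into channels. Its closed forms (0 for uniform;
$\sqrt{k-1}$ for all mass in one of $k$ bins) anchor the tests.

## The synthetic generators: what they emulate, and what they do not

The generators exist so that every analysis stage has an input with exactly
known ground truth.

* `gen_walkers()` produces an ensemble of rigid ideal water molecules
  (O–H 0.9572 Å, H–O–H 104.52°, fixed random orientation per molecule)
  rigidly translated along walker paths. In `brownian` mode each step per
  axis is Gaussian with variance $2 D \Delta t$, so the ensemble MSD is
  $6 D \tau$ in expectation *exactly* — parameter recovery is a sharp test.
  `ballistic` mode (constant random velocity) gives $\mathrm{MSD} =
  (v\tau)^2$ exactly; `confined` mode adds specular reflection at a
  spherical cavity wall, the simplest mechanism that produces the
  linear-to-plateau crossover of restricted diffusion. The default frame
  spacing of 5 ps matches a typical production-MD recording interval. The
  generator refuses specs whose step size exceeds $L/4$, which would make
  unwrapping ambiguous by construction.
* `gen_cluster_scene()` plants clusters of prescribed sizes: each cluster is
  grown as a connected blob (every member within the linkage cutoff of an
  earlier member, no two members closer than 2.2 Å) and blobs are placed
  with all inter-cluster distances beyond `min_gap > cutoff`, optionally
  translating the largest cluster onto a box face to exercise the periodic
  path. The generator re-clusters its own output and retries (bounded)
  until the planted partition is the unique single-linkage result, so the
  returned partition is a certificate, not a hope.
* `gen_hbond_scene()` builds explicit D–H···A–X groups realizing requested
  (distance, donor angle, acceptor angle) triples exactly, 20 Å apart on a
  grid so no unintended contacts arise. Only the bridging hydrogen is
  donor-flagged and only A acceptor-flagged, so each triplet contributes at
  most one candidate bond. For water acceptors the acceptor angle is
  vacuous (no heavy neighbour); angle-threshold scenes therefore use
  polymer acceptors.

What passing these tests does **not** show: the walkers have no
intermolecular forces, no hydrodynamic coupling, no coupling between
position and orientation, and the box does not fluctuate. Agreement on
synthetic input validates the *estimators* — that the MSD machinery, window
detection, unit conversion, clustering and counting are correct — not the
physics of any particular simulated material. Quantities that depend on
force-field physics (actual diffusion coefficients of a resin, actual
hydrogen-bond populations) can only come from real MD input.

## Numerical and engineering choices

* **Indexing.** Atoms, molecules and frames are 1-based throughout, as is
  idiomatic in R; bins and windows are half-open `[a, b)`.
* **Pair search.** Neighbour searches (hydrogen-bond candidates, cluster
  links) use exact vectorised all-pairs minimum-image distance evaluation,
  chunked to bound memory. At the system sizes this package targets
  (thousands of atoms), vectorised $O(n^2)$ arithmetic in R is faster than
  an interpreted cell-list loop and is exactly equivalent to the brute-force
  oracle by construction; the chunk size bounds peak memory at a few
  megabytes.
* **Reproducibility.** Every generator takes an explicit seed and restores
  the caller's RNG state; identical spec + seed gives bit-identical output.
  The pipeline writes a manifest with an MD5 checksum per artifact and a
  hash of the configuration, and identical config + inputs + seed produce
  byte-identical numeric outputs.
* **Degenerate inputs.** Zero-diffusion specs freeze the ensemble; empty
  species selections warn rather than error; a zero-mean equilibration
  series switches the drift criterion from relative to an absolute
  threshold that must be supplied; a negative fitted MSD slope is an error,
  not a negative diffusion coefficient.
* **Validation problem sizes.** The parameter-recovery suite uses Brownian
  ensembles of 500 walkers × 2000 frames at the two resin-scale diffusion
  coefficients and 3000 walkers × 600 frames at the bulk-water scale,
  recovering each prescribed $D$ within 5% on the auto-detected window;
  oracle-equivalence suites run to 10 molecules × 50 frames (MSD), 200
  scenes of up to 60 atoms (hydrogen bonds) and 200 molecules (clustering).
  These sizes give sampling errors comfortably inside the asserted
  tolerances while keeping the default test run fast.

## Equilibration check

`equilibration_drift()` quantifies the "steady profile" judgement usually
made by eye: a least-squares slope over the tail (default the last half) of
a monitored scalar series, passing when the total drift across the tail is
at most 1% of the tail mean. It is a screening statistic, not a rigorous
stationarity test — a series can drift slowly inside 1% and still be
unequilibrated — and it is reported alongside, not instead of, the analyst's
inspection.

## Known limitations

* Orthorhombic boxes only; triclinic cells are rejected at input. No
  affine correction for NPT box fluctuations is applied to the MSD (the
  per-frame box is honoured for wrapping and minimum image, but unwrapped
  paths are used as stored); at ambient-condition fluctuations this is a
  second-order effect.
* Text trajectory formats only (XYZ with a `Lattice` comment, multi-model
  PDB, GRO); no DCD/XTC.
* No velocity-based (Green–Kubo) diffusion, no per-axis anisotropic $D$,
  no finite-size hydrodynamic corrections.
* Hydrogen-bond definitions are geometric only (no energetic criterion) and
  no bond lifetime/autocorrelation analysis is provided.
* Cluster statistics are per-frame; percolation and lifetime kinetics are
  out of scope.
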