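---
title: "A dynamically triangulated Monte-Carlo model of vesicles with curved active proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamically triangulated Monte-Carlo model of vesicles with curved active proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

`vesimc` simulates a closed lipid-bilayer vesicle as a dynamically
triangulated surface.  Vertices represent membrane patches of either bare
bilayer or a curved membrane-protein complex (CMC) — a coarse-grained stand-in
for protein assemblies such as BAR-domain or WAVE complexes that bend the
membrane and can recruit actin polymerization.  All lengths are measured in
units of the minimal tether length $\ell_{min}=1$ and all energies in units of
$k_BT=1$.

The configuration energy has three parts:

$$E \;=\; \sum_{i\in V} \frac{\kappa}{2}\,\bigl(2h_i - \rho_i C_0\bigr)^2 A_i
\;-\; \sum_{(i,j)\in E} w_{s_i s_j}\,\rho_i\rho_j
\;-\; \sum_{i \in V} w_{ad}\,\theta\!\left(\ell_{min}-|z_i - z_0|\right)$$

* **Bending** — a discretized Helfrich energy.  $h_i=(C_1+C_2)/2$ is the mean
  curvature at vertex $i$, computed from the cotangent mean-curvature vector
  with barycentric vertex areas $A_i$ (one third of each incident triangle).
  The sign of $h_i$ is taken against the outward vertex normal, so a sphere
  of radius $R$ has $h=1/R>0$ everywhere and a bare sphere has total bending
  energy $8\pi\kappa$ independent of $R$.  A CMC of species $s$ shifts the
  preferred total curvature $2h$ to its spontaneous curvature $C_0(s)$
  (convex $>0$, concave $<0$); bare vertices have $C_0=0$.
* **Binding** — each mesh edge joining two CMCs contributes $-w$ per bond.
  $w$ generalizes to a symmetric per-species matrix: a uniform matrix gives
  *universal* binding, a diagonal matrix *type-exclusive* binding.  Bare
  membrane never binds.
* **Adhesion** — with a rigid wall at $z=z_0$, every vertex within
  $\ell_{min}$ of the wall gains $-w_{ad}$.  Adhesion is energetically
  favourable (it must be, for vesicles to spread); the membrane can never
  cross the hard floor at $z_0-\ell_{min}$.

Membrane tension is not modelled explicitly; the total area is conserved
emergently (to within a few percent) by the hard edge-length bounds.  The
enclosed volume is unconstrained.

## Monte-Carlo dynamics

A sweep consists of $V$ vertex-move attempts on uniformly random vertices
followed by $E$ bond-flip attempts on uniformly random edges.  Vertex moves
propose a uniform displacement in a cube of half-width 0.15 (configurable;
chosen to put the move acceptance near 40–50%).  Bond flips replace the
shared edge of two adjacent triangles by the opposite diagonal, keeping the
membrane fluid: lateral diffusion of vertices (and of the proteins riding on
them) happens exclusively through flips.

Hard constraints are enforced by rejection: every edge must satisfy
$\ell_{min} < \ell < \ell_{max}$ with $\ell_{max}=1.7$ (a standard choice for
this simulator family which, together with the hard-core repulsion below,
keeps the surface self-avoiding); no vertex may approach a non-neighbour
closer than $\ell_{min}$ (checked with a uniform spatial grid of cell size
$\ell_{min}$, so the cost per proposal is O(1)); and no vertex may cross the
wall floor.

A move is accepted with the Metropolis probability
$\min\{1, e^{-\beta(\Delta E + W)}\}$, where the active work of a CMC vertex
displaced by $\delta\vec{x}$ is $W=-f\,\hat{d}\cdot\delta\vec{x}$.  The work
term is unbounded from below, so active systems ($f>0$) are genuinely out of
equilibrium; with $f=0$ the chain satisfies detailed balance.  $\beta$
defaults to 1 and is exposed only to scan a temperature axis.

### Active force direction and inhibition

For a normal-force species the direction $\hat d$ is the outward vertex
normal, evaluated just before the move.  An *aligned* species instead uses a
Vicsek-like weighted average
$\hat d_i = \widehat{\hat n_i + s\sum_j \hat n_j}$, where $j$ runs over CMC
vertices of the same connected cluster within Euclidean distance $r$ of $i$
(neighbours are weighted uniformly within the range, as the interaction is
stated).  This mimics the force alignment produced by cross-linked actin
bundles inside filopodia.  Directions are refreshed lazily: a full refresh at
the start of each sweep bounds the staleness at one sweep, and the moved
vertex's own normal is always current.  If the alignment sum cancels to zero
the outward normal is used.

Two inhibition modes model concave proteins that suppress actin recruitment
on their neighbours: *proportional* scales the force by the fraction of
non-inhibiting neighbours; *disabling* removes it entirely if any neighbour
inhibits.

## Mesh construction

The initial vesicle subdivides each face of a pentagonal dipyramid into
$n_{shell}^2$ triangles, giving exactly $V = 5\,n_{shell}^2+2$ vertices
($n_{shell}=30$ gives the reference 4502-vertex vesicle with 13500 edges and
9000 triangles).  The faceted surface has all edges exactly equal; it is not
projected onto a sphere because the projection would spread the edge lengths
beyond the $\ell_{max}/\ell_{min}$ window, and Monte-Carlo equilibration
rounds the shape within a few hundred sweeps anyway.  The default initial
edge length of 1.35 is the mean edge length of the equilibrated fluid
membrane under the default bounds, so the total area is conserved from the
first sweep rather than relaxing towards its fluid value.

Analytic test meshes are built separately: an icosphere (`make_sphere_mesh`)
for the $h=1/R$ and $8\pi\kappa$ limits, a cylinder patch ($h=1/(2R)$ in the
interior) and a flat patch ($h=0$).  On open patches boundary vertices have
no defined curvature and are excluded from bending sums.  The cotangent
discretization with barycentric areas is accurate pointwise at regular
valence-6 vertices (&lt;1%); at the 12 irregular valence-5 seed vertices of an
icosphere the pointwise error is O(10%), while integrated energies remain
accurate to better than 1% — this is why pointwise curvature tests are scoped
to regular vertices.

## Shape and cluster statistics

Per snapshot the package measures: connected CMC clusters (components of
CMC-occupied vertices under mesh edges, ignoring species, so mixed patches
count as one cluster); the mean cluster size and a restricted mean over
clusters smaller than 10 (the restricted variant separates the gas phase
without being swamped by a few giant clusters); the ordered gyration-tensor
eigenvalues $\lambda_1^2\le\lambda_2^2\le\lambda_3^2$ (position covariance
about the centre of mass — small $\lambda_1^2$ means flat, small
$\lambda_2^2$ elongated); the mean CMC–bare boundary length per CMC
$\bar\ell_p$, a *count* of boundary edges per cluster vertex (the
geometric-length variant is available as an option, but the published phase
thresholds 0.375 and 1.875 are per-CMC counts); and the segregation factor
$S = 2P(\text{same-type CMC neighbour})-1$ of mixtures.

The phase classifier applies an ordered decision list — gas (restricted mean
size &lt; 1.5), pearling ($\bar\ell_p<0.375$), flat ($\lambda_1^2<50$),
elongated ($80<\lambda_2^2<150$), buds ($\bar\ell_p\ge1.875$), else mixed.
The thresholds are calibrated at the 4502-vertex reference size and stored as
configuration; no automatic rescaling with $V$ is attempted, so labels on
much smaller vesicles are indicative only.

The cross-sectional area of a sack neck ("hole") is the magnitude of the
polygon vector area $\tfrac12|\sum_k \vec x_k\times\vec x_{k+1}|$ of a
user-supplied vertex loop; necks are picked by the user (e.g. in ParaView),
not detected automatically.

## Tube-transition theory

A hemispherical CMC cap of radius $2/C_0$ both minimizes bending and
maximizes the pulling force.  Balancing its total force
$F_{pull} = f\cdot\tfrac12\cdot 2\pi(2/C_0)^2/s_0$ (with $s_0$ the area per
vertex and the factor $\tfrac12$ from the hemisphere geometry) against the
classic membrane-tether restoring force $2\pi\kappa/r$ at $r=2/C_0$, i.e.
$\pi\kappa C_0$, gives the cubic phase boundary

$$f^* = A\,C_0^3, \qquad A = \frac{\kappa\,s_0}{4}.$$

The printed form of the restoring force is typographically ambiguous; the
tether-force reading used here is the unique one that produces the cubic
boundary with $A=\kappa s_0/4$ matching the reference value $A\approx10.6$
at $\kappa=28.5$ for a physically sensible $s_0\approx1.48\,\ell_{min}^2$.
$s_0$ is *measured* (mean $A_i$ of an equilibrated passive vesicle), not
assumed.  For CMC mixtures the effective parameters are per-CMC means of
$C_0$ and $f$; the revised variant excludes concave CMCs sequestered inside
internalized sacks (those without any convex neighbour).

## Parameters at a glance

| parameter | units | default | meaning |
|---|---|---|---|
| `kappa` | $k_BT$ | 20 | bending modulus (28.5 for the stiffer scans) |
| `w` | $k_BT$/bond | 1 | CMC–CMC binding (scalar or species matrix) |
| `c0` | $1/\ell_{min}$ | 1 | spontaneous curvature per species |
| `f` | $k_BT/\ell_{min}$ | 0–1 | active force per CMC |
| `w_ad` | $k_BT$/vertex | 0 | wall adhesion |
| `s`, `r` | —, $\ell_{min}$ | 0, 0 | alignment weight and range |
| `step` | $\ell_{min}$ | 0.15 | vertex-move half-width |
| `lmin`, `lmax` | $\ell_{min}$ | 1, 1.7 | hard edge bounds |
| `beta` | $1/k_BT$ | 1 | inverse temperature |

## What the synthetic fixtures emulate — and what they do not

The generators in this package (`build_vesicle`, `make_sphere_mesh`,
`make_cylinder_patch`, `make_plane_patch`, `plant_labels`,
`make_gyration_pointsets`) produce deterministic inputs with known analytic
properties: exact vertex counts, closed-form curvatures, planted cluster
shapes with countable boundary edges, and point clouds with closed-form
gyration spectra.  Correctness of the discretization is *defined* by
agreement on these analytic limits rather than by numerical identity with
any particular legacy implementation, whose internal curvature scheme is not
published.

Passing these tests shows that the energies, moves and measures are
implemented consistently; it does not show that desk-scale simulations
reproduce every collective phenomenon of the full-scale system.  Protein
transport is flip-limited: at any instant only ~1–2% of quads admit a legal
flip, so cluster coarsening from a dispersed initial state takes of order
$10^5$ sweeps at the reference size — the scale the original phase diagrams
were run at, and far beyond a test budget.  Desk-scale runs therefore probe
early-stage aggregation, local equilibrium and the *stability* of planted
configurations:

* the flat (pancake) phase is exercised by planting the rim-ring cluster and
  verifying that strong normal forces at low temperature flatten the vesicle
  ($\lambda_1^2$ collapses by an order of magnitude) while passive budded
  conditions do not;
* the segregation of normal- and aligned-force CMC mixtures starts from a
  rim band of mixed CMCs near the substrate (the analogue of the partially
  spread state used in the source protocol, which converts half the CMCs of
  a pre-spread vesicle) with the alignment range scaled to the vesicle
  radius ($r=7$ at $V\approx10^3$ versus 15 at the reference size).  With
  type-exclusive binding the segregation factor climbs steadily as same-type
  domains coarsen, but full phase separation ($S\approx0.9$) is a
  coarsening endpoint that reduced runs approach without reaching; with
  universal binding the rim stays near-perfectly mixed, and the residual
  segregation reported at full scale is carried by filopodia-like
  protrusions that only form at larger sizes and longer times.

Problem sizes used throughout the tests and the acceptance analysis:
vesicles of 502–982 vertices, runs of $3\times10^3$–$2.4\times10^4$ sweeps,
3–4 independent seeds per stochastic quantity.

## Numerical choices and degenerate inputs

* Curvature: cotangent weights with barycentric areas; degenerate (zero-area)
  triangles raise an error naming the triangle.  Inside the engine they
  cannot occur: the edge bounds make the most degenerate legal triangle
  (sides 1, 1, 1.7) still have area ≈ 0.36.
* The Metropolis rule always consumes exactly one uniform draw per decision,
  making trajectories bit-reproducible for a given seed; rejections by hard
  constraints consume none.
* Bond flips are exact connectivity involutions; a rejected flip is undone by
  flipping again, which restores the adjacency exactly (triangle identities
  may swap roles).
* The incremental energy of a move is computed from the moved vertex and its
  1-ring only — with this discretization no second-ring curvature changes —
  and matches a full recomputation to 1e-8 relative or better.
* Aligned force directions falling below norm $10^{-12}$ (antiparallel
  cancellation) fall back to the outward normal.
* Equal-seed runs are bit-identical; the seed and the resolved configuration
  are echoed into every output directory.

## Known limitations

Genus-0 topology only; no fission or fusion; no explicit tension, volume
constraint, osmotic pressure, hydrodynamics (sweep count is not physical
time), anisotropic CMC curvature, or contractile (myosin-like) forces.
Cluster identity is not tracked across snapshots beyond what the per-cluster
tables allow.  Phase labels at strongly reduced vesicle sizes should be read
with the threshold caveat above.
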