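---
title: "Methods: twistable worm-like chain models of DNA under force and torque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twistable worm-like chain models of DNA under force and torque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twlc)
```

## The physical model

Double-stranded DNA under tension and torsion is modelled as an inextensible
twistable elastic rod.  A molecule of `n_bp` base pairs is discretized into
`N = round(n_bp / q)` rigid segments of `q` base pairs each (default
`q = 1.5`); segment `n` carries an orthonormal body frame
$(\hat u_n, \hat v_n, \hat t_n)$ obtained from the laboratory frame by the
z--y--z Euler rotation $R_n = R_z(\alpha_n) R_y(\beta_n) R_z(\gamma_n)$, with
the stretching force along $+\hat z_0$.  The elastic energy (in units of
$k_BT$) is the discrete worm-like-chain form

$$E = \sum_n \frac{a}{2}\,|\hat t_{n+1}-\hat t_n|^2
      + \sum_n \frac{c}{2}\,(2\pi\,\Delta Tw_n)^2
      - b f \sum_n \hat z_0\cdot\hat t_n - 2\pi\tau\,\Delta Lk ,$$

where $a = L_p/b$ and $c = L_{tw}/b$ are the dimensionless bending and
twisting stiffnesses of one segment of length $b$ (nm),
$\Delta Tw_n = [\hat u_n\times\hat u_{n+1}]\cdot\hat t_n / 2\pi$ is the local
twist increment, $f$ is the force in $k_BT$/nm and $\tau$ the torque in
$k_BT$.  The linking-number change $\Delta Lk = Tw + Wr$ decomposes into
twist and writhe (Călugăreanu--White).  Two writhe evaluations are provided:

* the exact **Gauss double sum** over mutual solid angles of all
  non-adjacent segment pairs (closed form for straight segment pairs,
  validated in the tests against brute-force double quadrature of the Gauss
  integrand), and
* **Fuller's single-sum surrogate**
  $\Delta Lk_F = (\tilde\alpha_N+\tilde\gamma_N-\tilde\alpha_1-\tilde\gamma_1)/2\pi$,
  $Wr_F = \Delta Lk_F - Tw$, built from the *unwrapped* Euler angles.
  Fuller's form is exact for conformations reachable from the extended state
  without the tangent crossing $-\hat z_0$; it fails for interwound
  plectonemes (both behaviours are exercised by the solenoid and plectoneme
  fixtures).

## Structural states

Four duplex forms coexist: B (reference), L (left-handed), P (overwound) and
S (overstretched).  Each has its own persistence lengths, base-pair rise
(`contour_ratio` relative to B's 0.33 nm), helical repeat `h` with an
explicit handedness sign, base-pairing penalty $\mu_u$ ($k_BT$/bp, zero for
B) and Fuller-correction weight $\lambda_u$.  The packaged defaults
(`dna_state_params()`) are the commonly used literature values; the relaxed
linking density of state $u$ is
$\Delta lk_0(u) = \pm 1/h_u - 1/h_B$ (turns per bp), positive sign for
right-handed helices, i.e. $-0.159$, $0.237$ and $-0.068$ for L, P and S.
The table is read and written as YAML so users can supply their own
calibrations.

Temperature enters only through unit conversion (defaults to 298.15 K,
$k_BT \approx 4.116$ pN nm); all internal quantities are thermal.

## Monte Carlo sampler

`metropolis_sample()` draws equilibrium conformations of a homogeneous
B-state chain from $e^{-E}$ with the **Gauss** writhe in the torque term
(no locality approximation).  Moves are crankshaft rotations about a chord,
tail pivots, and local twist updates; acceptance is the Metropolis rule.
Rigid-block moves change the writhe only through moved-vs-unmoved pair
terms, which is what the incremental update computes (the update is asserted
against full recomputation in the tests).  Crankshaft spans are windowed to
bound that cost; pivots may regrow any tail so the global extension
relaxes quickly; a torque-free Boltzmann random walk (direct inverse-CDF
sampling of the bend angles) is used as the starting state.  Statistical
errors use batch means with at least 20 batches, plus an integrated
autocorrelation estimate.  Self-avoidance is off by default (the
torque-ensemble energy does not forbid strand passage); an optional
hard-core diameter rejects moves that bring non-adjacent segments closer
than the set distance.  This is a documented physical simplification, not an
approximation of the writhe itself.

## Transfer-matrix partition function

The analytic route expands the per-junction Boltzmann factor over Wigner
D-functions.  The single-state transfer matrix is

$$S_{kk'} = \pi^2\sqrt{(2k+1)(2k'+1)}\,e^{-a-c}
\sum_{p,s,s',r}(2p+1)(2s+1)(2s'+1)\,
e^{ir(\omega-\pi/2)} I_r\!\big(\tau(1-\tfrac{\lambda}{2\pi})\big)
I_r\!\big(c\sqrt{1+\chi^2}\big)\,
L^p_r(-a) L^s_r(-bf) L^{s'}_r(0)
\begin{pmatrix}p&s&k\\-r&r&0\end{pmatrix}^{\!2}
\begin{pmatrix}p&s'&k'\\-r&r&0\end{pmatrix}^{\!2},$$

with $\chi = \tau\lambda/2\pi c$, $\omega = \arctan\chi$, and
$L^k_r(s) = \int_{-1}^1 d^k_{rr}(\arccos x)\,e^{-sx}\,dx$ the bilateral
Laplace transforms of the diagonal Wigner small-d elements.  The boundary
vector is $V_k = 8\pi^2\, i_k(bf)\sqrt{2k+1}$ (free ends), and
$\ln Z = \ln \mathrm{Tr}(S^{N-1}V)$.

This expansion corresponds to a junction kernel in which the twist energy is
$c(1-\cos\varphi)$, the $\tau\lambda$ twist coupling is
$(\tau\lambda/2\pi)\sin\varphi$, and the Fuller linking increment is
periodicized per junction as
$(\tau(2\pi-\lambda)/2\pi)\sin(\Delta\alpha+\Delta\gamma)$ — the
Jacobi--Anger identity is what produces the two Bessel factors and the
$e^{-ir\pi/2}$ phase.  The test suite verifies this correspondence directly:
for a two-segment chain, $\mathrm{Tr}(SV)$ matches 4-D quadrature of that
kernel to $10^{-3}$ at soft stiffness, and the field-free closed form
$64\pi^4 e^{-a-c}I_0(c)\sinh(a)/a$ to machine precision.  All small-angle
forms agree with the printed discrete energy to $O(\varphi^4)$ per junction,
i.e. within the $b \ll L_{tw}$ regime where the discretization is valid
anyway.

Numerical choices:

* **Real assembly.**  The $+r$ and $-r$ harmonics pair into
  $2\cos(r(\omega-\pi/2))$; every matrix entry is real, so the imaginary
  residual of $Z$ is identically zero.
* **Scaling.**  $e^{-a}$ is folded into the Laplace transforms (integrands
  $e^{a(x-1)}\le 1$) and $e^{-c}$ into exponentially scaled Bessel
  functions; no intermediate leaves double range even for $a, c \sim 200$.
* **Cost structure.**  The quadruple sum is contracted once per
  $(a, bf)$ into a torque-independent stack of matrices $T_r$; any torque
  merely reweights the stack.  Torque sweeps, occupancy derivatives and the
  constant-$\chi$ linking derivative therefore cost a fraction of a second
  each at $k_{\max}=40$, $N \approx 6700$.
* **3-j tables.**  Squared 3-j symbols are generated by Gauss--Legendre
  projection of the product identity
  $d^p_{rr} d^s_{rr} = \sum_k (2k+1)(3j)^2 P_k$ — exact for polynomial
  degree below the node count — and are asserted against the Racah formula.
* **Truncation.**  All harmonic orders share one cutoff `kmax`
  (default 40 for production curves; adaptive mode raises it until
  $\ln Z$ is stable to $10^{-6}$ relative).  Observables are stable to
  better than 0.1% from `kmax` ≈ 30; the absolute $\ln Z$ retains a slowly
  decaying tail $\sim e^{-p^2/4a}$ and is reproducible to about $10^{-5}$
  relative under cutoff doubling, which is far below anything observable.
* **Derivatives.**  Extension $z = \partial\ln Z/\partial f$ and occupancy
  derivatives use Richardson-extrapolated central differences (relative
  step $10^{-3}$).  The linking number is the constant-$\chi$ derivative:
  $\chi$, $\omega$ and the twist Bessel argument are frozen while the
  argument of $I_r(\tau(1-\lambda/2\pi))$ and the per-state structural
  prefactors are shifted additively; this yields the physical
  $\langle\Delta Lk_F\rangle$ plus structural terms.  (Differentiating the
  explicit $\tau$ naively at fixed $\chi$ would return
  $(1-\lambda/2\pi)\langle\Delta Lk_F\rangle$, which disagrees both with
  the Monte Carlo $\langle Tw + Wr\rangle$ and with the magnitude of the
  superhelical-density jumps at the structural transitions.)

## Multistate block matrix and observables

State $u$'s transfer matrix is the single-state $S(a_u, b_u, c_u, \lambda_u)$
times $e^{-q(\mu_u - 2\pi\tau\,\Delta lk_0(u))}$.  The four-state block
matrix repeats each state row across the block columns, so it factors as
$\hat S = C\,J$ with $J = (I\,I\,I\,I)$; powers collapse onto
$M = \sum_u S_u$ and the boundary sum $w = \sum_u \mathrm{pref}_u V(b_u)$ —
the implementation uses this collapsed form and the tests confirm exact
agreement with the single-state limit when the other penalties are sent to
$+\infty$, and the $\ln 2$-per-segment shift for a duplicated state.

Occupancies are $N_u/N$ with
$N_u = -(1/q)\,\partial \ln Z/\partial\mu_u$ (central difference, step
$10^{-3}\,k_BT$).  `response_curves()` sweeps force or torque;
`phase_diagram()` locates the 50%-occupancy contours of L, P and S by
bisection along torque (0.1 pN nm resolution) and the supercoiling
boundaries where the computed extension falls to 50% of the Marko--Siggia
worm-like-chain extension of the locally dominant state (that state's
$L_p$ and contour length).

## What the fixtures emulate — and what they do not

The deterministic fixtures (straight, circle, solenoid, plectoneme) and the
Boltzmann random walk generate every input the tests need at run time;
no external data are involved.  They emulate the geometry and statistics of
the discretized rod model only: there is no sequence dependence, no salt or
temperature dependence of the parameter table, no base-pair-level structure,
and the default ensembles allow strand passage.  Passing tests therefore
validate the statistical mechanics of the model, not the biochemistry of any
particular DNA molecule.

## Known limitations

* **Post-buckling branch.**  Beyond the torque-collapse threshold the
  partition function is dominated by configurations with tangents near
  $-\hat z_0$, where the periodicized Fuller term accrues winding at almost
  no bending cost — the model's surrogate for the supercoiled state.  The
  computed extension there can be strongly negative (down to
  $\approx -0.97\,L_B$); it is converged in `kmax` and is intrinsic to the
  $\lambda$-corrected Fuller energy, which is quantitative only up to the
  buckling boundary.  Boundary *locations* (steep extension drops,
  occupancy crossings) remain well defined and are what the phase diagram
  uses.  A practical consequence: the torque-extension profiles acquire
  large $\pm\tau$ asymmetries at low force wherever the collapse thresholds
  of the two signs differ (the L state shifts the negative side), so the
  symmetric-profile regime claimed for $f < 0.5$ pN is not reproduced by
  the raw extension observable.
* **Marko--Siggia accuracy.**  The torsionless transfer matrix agrees with
  an exact continuum worm-like-chain eigenvalue computation to the
  discretization level (~1%).  The Marko--Siggia interpolation itself
  deviates from the exact solution by up to ~7% around
  $fL_p \sim k_BT$ (0.05--0.3 pN for B-DNA); comparisons against it are
  only meaningful above roughly 0.5 pN.
* **Monte Carlo scale.**  The sampler's writhe bookkeeping costs
  $O(\text{window}\times N)$ per move; the shipped tests use 200--300 bp
  chains and a few hundred to a couple of thousand sweeps, which gives
  standard errors of a few tenths of a percent on the extension — the
  problem sizes were chosen so the whole suite stays desk-scale while the
  transfer matrix (exact at any $N$ for the same discrete model) provides
  the comparison values.

## Worked example

```{r, eval = FALSE}
params <- dna_state_params()
chain <- chain_spec(10000, q = 1.5, params)

# torque-extension curve at 5 pN: the B-to-L step sits near -11 pN nm
curve <- response_curves("torque_extension", fixed = 5,
                         sweep = seq(-16, 0, by = 2), chain,
                         trunc = tm_truncation(kmax = 40), params = params)
curve[, c("tau_pNnm", "z_over_LB", "sigma", "occ_B", "occ_L")]

# phase boundaries on a small grid
phase_diagram(f_grid_pN = c(5, 20), tau_range_pNnm = c(-25, 50),
              chain = chain, trunc = tm_truncation(kmax = 40))
```
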