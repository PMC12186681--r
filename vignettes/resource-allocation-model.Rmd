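---
title: "A whole-cell resource allocation model of bacterial gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-cell resource allocation model of bacterial gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellecon)
```

## The model

`cellecon` simulates a coarse-grained bacterium in which every expressed
gene competes for two shared pools of machinery: RNA polymerase on
promoters and ribosomes on mRNAs.  The host is reduced to five lumped
transcription units — metabolic enzymes (`E`), housekeeping bulk (`Q`), RNA
polymerase (`P`), ribosomal protein (`R`) and ribosomal RNA (`rrn`, which is
transcribed but never translated) — to which synthetic circuit genes and a
product pathway can be attached.  The state of a cell is a vector of
molecule counts: external substrate $S$ and population $N$ (culture level),
an internal metabolite pool $M$ standing in for amino acids, nucleotides
and ATP, uncharged and charged tRNA ($t_u$, $t_c$), one mRNA and one
protein count per translated gene, free rRNA $r$, assembled ribosomes
$R_{tot}$, and antibiotic-sequestered polymerase/ribosome pools.

**Metabolism.** Enzymes import substrate at rate
$v_E S p_E/(\kappa_E + S)$, each substrate molecule yielding $\phi$
metabolites.  tRNAs are charged at rate
$v_T p_E / (1 + K_u/t_u + K_M/M)$, consuming one metabolite and one
uncharged tRNA per charging event; this single flux appears with opposite
signs in $dM/dt$, $dt_u/dt$ and $dt_c/dt$, so the charging cycle conserves
material by construction.  Uncharged tRNA is produced at a maximum rate
$\psi_{max}$, scaled by the same regulation function as the other
ribosomal components.

**Elongation.** The global transcript elongation rate saturates in the
metabolite pool, $\tau_X(M) = \tau_{max} M/(K_\tau + M)$, and a gene of
$n_j$ codons completes transcripts at $\tau_X/(3 n_j)$.  Peptide
elongation saturates in charged tRNA,
$\gamma_X(t_c) = \gamma_{max} t_c/(K_\gamma + t_c)$, and a protein of
$n_j$ residues is completed at $\gamma_X/n_j$.  rRNA elongates at the
constant $\tau_{r,max}/n_r$; the option `rrn_M_dependent` switches it to
share the metabolite saturation of mRNA elongation, preserving an
alternative reading of the defining equations (the derivative of free rRNA
is written with a metabolite-dependent rate while the rate itself is
defined as a constant; the definition wins by default, and the switch
keeps the other reading available).  The same conflict arises for protein
synthesis, which is written against $M$ but defined against $t_c$;
translation here uses $t_c$, matching the definition.

**Quasi-steady-state competition.** Promoter–polymerase and mRNA–ribosome
binding are assumed fast, so complex abundances follow algebraically from
the totals: gene $j$ holds
$\tilde k_j = K_{j,X} P_{tot} / (1 + \sum_i K_{i,X})$ polymerases, with
sequestration potential $K_{j,X} = g_j R_j / \kappa_{X,j}$ and
dissociation scale $\kappa_{X,j} = (k_{p,r} + \tau_j + k_{rf})/k_{p,f}$;
ribosome complexes $\tilde c_j$ follow the same form with
$K_{j,L} = m_j/\kappa_{L,j}$, $\kappa_{L,j} = (k_{r,r} + \gamma_j +
k_{cm})/k_{r,f}$.  The rRNA gene competes for polymerase but never for
ribosomes.  These partitions conserve the pools exactly at every
evaluation, which the test suite checks at thousands of random states.

**Growth.** The growth rate is total translational capacity over cell
mass, $\lambda = \gamma_X \sum_j \tilde c_j / M_0$.  At steady state this
makes total protein mass equal $M_0$ automatically.  Effective gene copy
numbers expand with growth, $g_j = g_{0,j} e^{q_x \lambda}$, capturing
replication-associated dosage; $\lambda$ is evaluated from the current
state (well-posed because $\lambda$ depends only on the translation side,
never on $g_j$).

**Regulation.** All regulation runs through an alarmone proxy
$\theta = t_c/t_u$, effectively the inverse of the stringent-response
alarmone level.  Ribosomal components and polymerase are activated by
translational sufficiency, $R = \theta/(\theta + \kappa_\theta)$; the
enzyme sector is activated by scarcity, $R_E = \kappa_\theta/(\theta +
\kappa_\theta)$ (so $R_E + R_P = 1$); housekeeping genes are negatively
autoregulated, $R_Q = 1/(1 + (p_Q/\kappa_q)^{h_q})$ with $h_q = 1$ by
default ($h_q$ is exposed because the feedback is printed without an
exponent; the literal reading is the default).  Circuit genes carry
$R_i = u_i \kappa_\theta/(\theta + \kappa_\theta)$ with induction $u_i \in
[0,1]$.  The perturbation $D_g$ multiplies $\theta$ before all regulation
functions — it scales the regulation variable itself, which is the most
direct reading of a knob said to scale the alarmone proxy.  Inside the
ratio only, $t_u$ is floored at $10^{-9}$ molecules so integrator trial
states at the boundary stay finite.

**Ribosome biogenesis.** Free rRNA and free r-protein associate at rate
$\beta_\rho p_r r$ into functional ribosomes, which disassemble at
$\mu_\rho R_{tot}$.  Antibiotic sequestration moves polymerase
($k_{rf}$) and ribosomes ($k_{cm}$) into inert pools that dilute but never
reactivate.

**Culture modes.** Single-cell mode freezes $S$ and $N$ (mid-exponential
growth at constant substrate); batch mode depletes a finite substrate
while the population grows; chemostat mode adds substrate influx $k_{in}$
and dilution $\delta$, with the interior fixed point pinned at
$\lambda^\ast = \delta$.

## Parameters

Units are molecules per cell and hours throughout; $M_0$ is in amino-acid
equivalents.  The fitted parameter values behind the original study are
not published, so the defaults shipped here are this package's own coarse
calibration to a scaled-down E. coli-like cell ($M_0 = 3\times10^6$ aa,
roughly $10^{-3}$ of a real cell so that desk-scale simulation is cheap):

* a maximum growth rate of about 0.85/h on saturating substrate, with
  chemostat steady states across 0.1–0.5/h;
* a ribosomal mass fraction rising from ~4% to ~21% and a peptide
  elongation rate rising with growth rate, the qualitative shape of the
  bacterial growth laws;
* charging and elongation operating below saturation ($K_u$, $K_\gamma$
  comparable to or above the operating pools).  This choice matters: when
  both fluxes saturate, the tRNA partition turns into a relaxation
  oscillator at low growth (both fluxes become pool-insensitive, so the
  partition integrates to a boundary and snaps back).  Sub-saturated
  operation restores proportional control and a clean fixed point;
* transcription only mildly metabolite-limited ($K_\tau = 2000$): with a
  large $K_\tau$ the metabolite collapse at slow growth starves
  transcription, idles ribosomes and makes the apparent elongation rate
  *fall* with growth — backwards relative to the growth laws.

Replace any of this with `cellModel(params = ...)` or a config file, or
calibrate against data with `fitParameters()`.

## Circuits, pathway, perturbations

`addCircuit()` appends reporter genes that enter both competition sums and
the growth-rate sum; `twoReporterCircuit()` is the standard two-reporter
configuration.  Circuit genes default to the host enzyme gene's kinetics
(documented so isocost slopes are interpretable) on a 40-copy plasmid, and
experience the same copy-number expansion as host genes (the option
`circuit_copy_expansion` disables this, since nothing pins the choice for
plasmids).  `addPathway()` attaches one lumped reaction draining the
metabolite $M$ into a product $X$ at rate $v_{ME} M p_1/(\kappa_{ME}+M)$
(a violacein-like pathway reduced to a single step, exactly as the model
it follows does); the flux leaves $dM/dt$ and enters $dX/dt$ with the same
magnitude.  The demo values $v_{ME} = 30$/h, $\kappa_{ME} = 300$ put the
drain in its saturating regime over the chemostat range, so product per
cell falls with dilution while the production flux $\lambda X$ peaks at
low growth.  `applyPerturbations()` composes the knobs: $D_r$ (rRNA gene
dosage, the continuous representation of rrn-operon deletion strains),
$D_\gamma$, $D_\psi$ (maximal elongation and tRNA supply, the
carbon-quality dials), $D_g$ (alarmone scaling) multiply, and the
antibiotic rates $k_{rf}$, $k_{cm}$ add.

## Simulation protocol

All simulations start from 100 molecules of every protein species
(including ribosomes) and $10^3$ molecules of $M$, $t_u$ and $t_c$; all
other species start at zero.  Integration uses the stiff solver (lsoda,
relative tolerance $10^{-8}$); small negative excursions are clipped to
zero inside the RHS.  `solveSteadyState()` follows the
horizon-doubling protocol — integrate, double the span, stop when the
maximal absolute derivative falls below $10^{-3}$ — with a damped-Newton
accelerator (Broyden-updated finite-difference Jacobian) whose result must
pass the same derivative check, so the convergence contract is identical
with or without it.  Newton is not allowed to jump from a growing state
onto the coexisting quiescent fixed point (the starvation lock-in branch
in which $\theta$ diverges, enzymes switch off and charging never
restarts): that branch is only accepted when the trajectory itself decays
into it.  Cold chemostat starts are seeded by continuation: the single-cell
problem is solved along a substrate ladder until growth crosses the
dilution rate, the population is sized from the substrate balance, and the
full system is then polished.  This avoids the violent wash-in transient
(population overshoot against the supply) that otherwise dominates cold
starts.  Sweeps (`runSweep()`, `isocostSweep()`) warm-start each grid
point from the previous one for branch continuity and speed; non-converged
points are flagged in the result table, never dropped silently.
Isocost fits are ordinary least squares of $p_2$ on $p_1$ over converged
points, with optional normalization of each reporter by its own maximum
over the sweep (the scaling used for relative-expression plots).

## Calibration

`growthLawCurves()` varies growth the way the fitting protocol
prescribes: through nutrient quality $\phi$ and translation inhibition
$k_{cm}$ in the exponential regime.  Each condition yields $\lambda$, the
ribosomal mass fraction $\Phi_R$, the global elongation rate $\Gamma$ and
$\theta$.  Errors are normalized sums of squares,
$\sigma = \sum(\mathrm{sim}-\mathrm{exp})^2 / \sum \mathrm{exp}^2$, and
the total cost is the weighted sum
$10\,\sigma_{\lambda,DB} + 5\,\sigma_{\lambda,Scott} +
5\,\sigma_{R,Scott} + \sigma_{R,DB} + \sigma_{\Gamma,DB} +
\sigma_{\theta,DB}$ over a Scott-type source (growth rate and ribosomal
fraction) and a DB-type source (all four observables).  Which $(\phi,
k_{cm})$ pair generated each experimental condition is not published
anywhere, so the dataset format carries explicit `phi` and `k_cm` columns
per row and the user (or the synthetic generator) supplies the mapping.
Failed candidate simulations cost a finite $10^6$ rather than raising, so
population optimizers keep moving.  `fitParameters()` is a
constriction-coefficient particle swarm (inertia 0.729,
cognitive/social weights 1.49, the standard constants) with the reference
protocol's 500 particles × 500 generations as defaults; it is
deterministic given a seed.

`synthGrowthLawData()` generates growth-law tables from a known model with
multiplicative Gaussian noise, standing in for the external growth-law
compilations so the calibration path runs entirely offline.  It emulates
the observable set and magnitude structure of those compilations, not
their biological scatter: real data carry condition-specific systematic
error, correlated replicates and model misspecification, none of which the
generator produces.  Recovery tests on it therefore show that the
optimizer and cost are sound — not that the model fits any particular
organism's measurements.

## The flux-capacity module

`addProteinDemand()` augments a stoichiometric network with one reaction
consuming a protein's amino-acid composition plus GTP per peptide bond
(default 2 — one GTP-equivalent each for delivery and translocation;
charging ATP costs are excluded; both choices are configurable because the
source protocol states only that amino-acid and GTP consumption were
added).  `maxProteinFlux()` maximizes the demand flux with carbon uptake
bounded and biomass fixed as an equality; `runFVA()` classifies reactions
as flexible when their flux range at the optimum exceeds 0.001 mmol/gDCW/h;
`subsystemNetFlux()` and `metaboliteNetFlux()` aggregate signed rates, in
total and through the inflexible core.  SBML-FBC serialization is
deterministic and round-trips; the reader also accepts group- or
note-annotated subsystems from published reconstructions.  The bundled LP
solver is a dense simplex, entirely adequate for the desk-scale fixture
(`toyNetworkFixture()`: two carbon sources of unequal yield, a redundant
parallel-path motif, twenty amino-acid syntheses, hand-computable optima);
a genome-scale reconstruction will load structurally, but solving it needs
a sparse LP backend, which is outside this package's scope.

## Numerical choices

* steady-state criterion $10^{-3}$ on the max absolute derivative, as the
  reference protocol prescribes; Newton polishes to $10^{-4}$ so the
  criterion is met with margin;
* integrator tolerances $10^{-8}$ (relative) / $10^{-6}$ (absolute);
* state clipping threshold 0 (any negative trial value is evaluated at 0);
* ties and degenerate inputs: zero uncharged tRNA is floored inside
  $\theta$ only; zero metabolite or tRNA pools simply zero the
  corresponding fluxes; an all-zero proteome makes mass fractions
  undefined and errors out.

Test and acceptance problem sizes were chosen to keep the full suite at a
few minutes on one core: conservation is checked at $10^4$ random states,
trend sweeps use 5-point grids, the recovery experiment fits 3 parameters
over 6 conditions with a 50 × 100 swarm, and the oracle comparison runs a
7-gene toy with ~30 mechanistic species.

## Known limitations

* **rRNA dosage sensitivity ordering.**  Reducing rRNA gene dosage
  ($D_r < 1$) lowers circuit expression monotonically at every dilution
  rate, as it should.  But across this package's default calibration — and
  every structural variant we probed (binding strengths, saturation
  regimes, $q_x$ up to 4, $\kappa_\theta$ over two decades, rRNA promoter
  share and speed, metabolite-dependent rRNA elongation, assembly
  equilibria) — the effect is *stronger at fast growth than at slow
  growth*: the slow-growth steady state carries spare translational
  capacity that buffers dosage cuts, while the published phenomenology has
  slow-growing cells as the sensitive regime.  The corresponding
  acceptance assertion is deliberately left failing rather than weakened;
  reproducing the published ordering presumably requires the original
  (unpublished) fitted parameter values.
* The model is deterministic and well-mixed: no stochastic gene
  expression, no spatial structure, no explicit alarmone molecule, and no
  stress-response regulon — at very low growth it therefore predicts
  heterologous expression levels beyond what stressed real cells reach.
* Default parameters are placeholders in the specific sense above:
  internally consistent and qualitatively right, but not fitted to any
  organism's data.  Quantitative claims require a user calibration.
* The quiescent (starvation lock-in) fixed point coexists with the growing
  branch; the steady-state solver tracks the physiological branch, but
  trajectories started from sufficiently distorted states can genuinely
  end there.
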