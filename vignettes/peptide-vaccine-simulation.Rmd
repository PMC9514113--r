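---
title: "Mechanistic simulation of short-peptide vaccine trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic simulation of short-peptide vaccine trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepvax)
```

## The scientific problem

Short (9-mer) peptide cancer vaccines deliver tumour-associated peptides
intradermally, hoping to prime CD8+ T-cell responses. Clinically, cohorts
given nine-peptide vaccines respond to strikingly few of them — most patients
to zero or one. `pepvax` implements a mechanistic explanation: short peptides
can only be presented by binding dendritic-cell (DC) surface MHC-I directly,
so they compete for a small receptor pool at the injection site, and whatever
is bound then dissociates at the peptide-specific off-rate $k_{off}$ during
the 20–40 hours that DCs need to reach the draining lymph node. Peptides with
half-lives short relative to that transit arrive with effectively no antigen,
and no parameter choice can rescue them.

The package chains three mechanistic stages into a per-patient, per-peptide
response probability, wraps them in a virtual-patient trial engine, and fits
population-level parameter distributions to an observed responder histogram
with Approximate Bayesian Computation (ABC).

## Stage 1: competition for MHC-I in the dermis

For each peptide $i$ with free concentration $l_i$, bound complexes $c_i$ and
free available receptor $r$ (all µM):

$$\frac{dl_i}{dt} = k_{off,i} c_i - k_{on} r l_i - k_{clear} l_i, \qquad
  \frac{dc_i}{dt} = k_{on} r l_i - k_{off,i} c_i,$$

with $r + \sum_i c_i = f_{avail}\, r_{tot}$ conserved. Association is taken
to be equal across peptides of equal size ($k_{on}$ shared); MHC-I affinity
differences are carried entirely by $k_{off}$. Defaults: $l_0 = 200$ µM per
peptide and $r_{tot} = 2\times 10^{-2}$ µM (10^5^ receptors per DC).
Because $l_0 \gg r_{tot}$, receptor filling is essentially instantaneous and
pseudo-first-order while clearance and dissociation act over hours — a stiff
system, integrated with `deSolve::lsoda` (automatic stiff switching) at
`rtol = 1e-8`, `atol = 1e-12`, stored on a log-spaced grid (400 points)
that resolves both the filling transient and the slow decay. Receptor
conservation is asserted to 10^-6^ relative on every solve.

Two rate constants are not identifiable from the trial data and are exposed
as configuration with the following defaults:

* `k_on = 1` µM^-1^h^-1^ — makes binding saturate within minutes at
  $l_0 = 200$ µM (pseudo-first-order rate 200 h^-1^), consistent with a
  receptor pool that is rapidly filled by the enormous free-peptide excess;
* `k_clear = 20` h^-1^ — vascular clearance of free small peptides on the
  minutes timescale, driving free peptide below 1% of $l_0$ well within
  two hours.

After clearance the equations collapse to $dA/dt = -k_{off} A$ for the bound
fraction $A$, which is also the transport model in the lymphatics (no free
peptide there, so rebinding is off by construction).

**The role of `f_avail`.** The patient parameter $f_{avail}$ is the fraction
of a DC's MHC-I available to vaccine peptides (the rest being occupied by, or
reserved for, endogenous peptide; self-peptide competition is otherwise not
modelled because only the cognate fraction matters to the activation
statistic). Since the available pool saturates regardless of its size, the
bound *fraction of the available pool* is insensitive to $f_{avail}$; what
the lymph-node stage needs is the cognate fraction among *all* contact-region
MHC-I, which is $f_{avail} \times A_i$. The trial engine performs exactly
this multiplication, making $f_{avail}$ act as the overall antigen-dose scale
per patient — this is the package's reading of "proportion of MHC-I available
to vaccine peptide" as a fitted patient parameter, and the only reading under
which it has any effect.

## Stage 2: DC migration and antigen decay

DC migration efficiency (fraction of activated dermal DCs recovered in the
draining node) is exponentially distributed with mean 1% (`rate = 100`),
truncated at `efficiency_cap = 0.03` by inverse-CDF sampling — published
measurements put essentially all mass below 3%. Truncating by (the analytic
equivalent of) resampling rather than clipping avoids an atom at the cap.
The migrated count is $D = \mathrm{round}(\text{eff} \times 600\,
\text{DC/mm}^2 \times 60\, \text{mm}^2)$, i.e. 360–1440 DCs at 1–4%
efficiency. Each vaccination visit draws its own efficiency: migration is an
injection-event property, not a fixed patient trait.

DCs leave the dermis at `t_depart` (default 6 h — they begin migrating
several hours after activation), spread their departures over $p$ hours, and
arrive after `transit_time` (default population mean 30 h). The first
arrival is at $P = t_{depart} + \text{transit}$ and arrivals proceed at the
constant rate $(D-1)/p$ (uniform-random arrivals on the same window are
available; they change results little). Surface antigen decays from each
DC's own departure: $A(t) = A_{depart} e^{-k_{off}(t - t_{dep})}$. Activated
DCs live 48 h in the node.

## Stage 3: T-cell search in the paracortex

The paracortex is a sphere of radius $R = 500$ µm containing
$n = \phi \rho V$ cognate T-cells ($\rho = 10^{-3}$ cells/µm³ fixed;
precursor frequency $\phi$ is the fitted patient parameter — only the product
matters). T-cells run-and-tumble: straight runs of exponentially distributed
length (mean $F = 25$ µm) at $v = 10$ µm/min with uniform reorientation;
a Lévy option (Pareto run lengths, shape 2, same mean) is provided. DCs are
stationary (`w = 0`; a positive DC speed enables the same walk for them).
The boundary is reflective — the model is of a closed, non-inflamed node with
conserved cell number; cells are reflected radially about the surface.

A contact begins when centre separation drops below $b = 10$ µm and cannot
recur for a pair until they separate beyond $b$ (otherwise one encounter
would be recounted every time step). The time step is
$\min(F, b)/v/4$ (0.25 min at defaults) so a cell cannot tunnel through a
contact shell in one step. On contact at time $t$ the interaction succeeds
with probability $P(X \ge T)$, $X \sim \mathrm{Binomial}(N, A(t))$: of
$N = 100$ MHC-I sampled in the contact region, at least $T = 10$ must carry
cognate peptide. The binomial stands in for the exact hypergeometric draw
from the DC's 10^5^ receptors; `activation_sampling_gap()` computes the
worst-case difference over all antigen ratios (about 10^-4^ at these sizes,
far below the 0.1 bound it is required to satisfy).

Because $A(t)$ only decreases, a cell whose first qualifying contact fails
would fail all later ones under any fixed per-cell threshold; the model
therefore reports the **maximum** probability of activation, accumulated
analytically per cell as $1 - \prod_i (1 - q_i)$ over its contacts rather
than by Bernoulli retirement (this also removes one layer of Monte-Carlo
noise). The two outputs are `p_per_cell(t)` and
`p_any(t) = 1 - \prod_{cells}(1 - p_{cell})`, both non-decreasing in $t$.
The per-dose response probability is `p_any` at the horizon, which defaults
to last DC arrival + DC lifetime; 6/12/24 h readouts are available from the
stored hourly grid. The biophysical defaults ($R$, $v$, $F$, $b$, $N$, $T$)
are literature-conventional scales, every one exposed in
`biophysical_params()`; no quantitative claim of the package depends on
their exact values.

The agent-based core is compiled (Rcpp) and uses its own `mt19937_64` stream
seeded per replicate, so results are bit-identical for a given seed
regardless of R's RNG state.

**Well-mixed surrogate.** For inference loops the spatial model is replaced
by a kinetic encounter process: one T-cell meets one stationary DC at rate
$\gamma = \pi b^2 v / V$ (swept contact volume over paracortex volume), and
the per-cell hazard is $\Lambda(t) = \gamma \sum_j \int_0^t q(A_j(s))\,ds$
over active DCs, giving $p_{cell} = 1 - e^{-\Lambda}$ and
$p_{any} = 1 - e^{-n\Lambda}$. Because every DC shares one decay curve
shifted by its departure, the integral is computed once and reused, making a
dose evaluation effectively instantaneous. The ballistic $\gamma$ ignores
the persistence correction of finite free paths; empirically the surrogate
tracks the ABM to within ~5–20% in the per-cell probability, and the tests
validate the ABM itself against the closed form using an encounter rate
estimated by an independent Monte-Carlo collision counter. The ABM remains
the reference model; the surrogate is the default only inside ABC.

## The trial engine

A virtual patient is a draw of $(f_{avail}, \text{transit}, p, \phi)$ from
independent Gaussians truncated to their admissible ranges by resampling
(rejection capped at 10^4^ rounds, after which cohort construction fails
loudly). For each patient and peptide, doses combine independently across
visits: $p_{resp,i} = 1 - \prod_v (1 - p_{dose,i,v})$, and the expected
number of responses is $\sum_i p_{resp,i}$. The cohort histogram of patients
responding to 0, 1, 2, 3+ peptides is computed in expected mode — each
patient contributes its exact Poisson-binomial mass (O(n²) convolution,
checked against exhaustive 2⁹ enumeration) — or in sampled mode (Bernoulli
draws), which is what the synthetic-data generator uses for observed
histograms, since real trials report integer counts. Whole trials are
repeated (default 3) with fresh cohorts to expose patient-sampling
variability; the 3+ aggregation level is a design-file field.

Intervention variants are pure design transformations: dropping peptides
(releasing dermal MHC-I to the survivors — a direct consequence of the
shared receptor pool) and overriding the population transit-time or spread
means (e.g. 30 h → 10 h, emulating faster-draining routes). Both reliably
increase the mean expected number of responses in the simulated trials.

## ABC fitting

The fitted quantities are the population means and SDs of the four patient
parameters (8 hyperparameters). Generation 1 samples uniformly from a prior
box; each particle simulates one trial and is scored by the root-mean-square
difference between simulated and observed histogram counts; the best 10%
are kept. Later generations resample accepted particles and perturb
component-wise with a Gaussian kernel of width twice the weighted particle
SD, reflected at the prior bounds. The loop stops early when the median
accepted score improves by less than 1% over two generations. Choices the
underlying procedure leaves open, fixed here as defaults: top-fraction
acceptance (standard ABC-PMC practice) rather than a fixed epsilon; one
simulated trial per particle inside the loop (repeat noise is absorbed by
the acceptance tolerance); the well-mixed surrogate as the inner forward
model, with the ABM available via `mode = "abm"`; joint perturbation of
(mean, sd) pairs. Posterior outputs are particle clouds and weighted 2D
kernel-density projections (normal-reference bandwidths, grid-renormalised)
— never point estimates, because the parameters are not identifiable from a
responder histogram and are not claimed to be.

## The synthetic-data generator

`synthetic_scenario()` emulates the structure of measured short-peptide
panels — a cluster of slow off-rates (half-lives 15–40 h) plus fast outliers
(0.1–1 h), random 9-mer sequences (cosmetic; only $k_{off}$ enters any
computation) — and a Gaussian ground-truth population
($f_{avail}: 0.5 \pm 0.1$, transit $30 \pm 5$ h, spread $10 \pm 2$ h,
$\phi: 2\times10^{-5} \pm 5\times10^{-6}$), chosen so that dose
probabilities sit mid-range and every histogram bin is populated. Observed
histograms are generated in sampled mode at the ground truth, giving
parameter-recovery experiments a known answer. What passing recovery shows
is internal consistency of the fitting machinery under the generator's
assumptions (independent Gaussian patients, exchangeable peptides sharing
$k_{on}$, exact forward model); it does not validate the biology against
real cohorts, where assay thresholds, per-peptide precursor frequencies and
HLA heterogeneity all intrude.

## Problem sizes and reproducibility

Routine runs and the shipped experiments use scenario defaults sized for a
single CPU: 12 patients, 5 peptides, 3 visits, 200 ABC particles over up to
6 generations with the well-mixed forward model (a few minutes); the
full-scale configuration of 10000 particles and 25 generations is reachable
by configuration alone. The ABM is used with 10 replicates per dose
evaluation in reference mode and 200 replicates in its validation against
the well-mixed closed form. Every stochastic entry point takes a seed;
patients, doses and particles get derived sub-seed streams, so trials and
fits are bit-reproducible.

## Known limitations

* No spatial dispersal of peptide or adjuvant in the dermis (fixed 0.6 cm²
  area, adjuvant assumed non-limiting), no lymphatic transport mechanics
  (transit is a delay plus exponential decay).
* No TCR-affinity spectrum: a single precursor frequency per patient, shared
  across peptides, consistent with reporting only a maximum activation
  probability; no downstream clonal expansion, cytokines or inflamed-node
  effects.
* On-rates assumed equal across peptides; if they differ, the initial bound
  composition — and hence which peptides are worth removing — changes.
* Immunological response is the sole endpoint; no survival or clinical
  efficacy modelling.
* Responder histograms carry little information about 8 hyperparameters:
  posteriors are broad and correlated by construction, and only
  distribution-level statements are meaningful.
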