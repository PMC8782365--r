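---
title: "Model dynamics: selfish risk-seekers and generous risk-averse agents in an ecological public goods game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggevol)
```

## The model

`pggevol` simulates the evolution of a community containing two behavioural
phenotypes over thousands of non-overlapping generations:

* **selfish risk-seekers (S)** harvest aggressively (a fraction
  $h_S = 0.8$ of the per-capita offer), contribute little to the communal
  pot ($c_S = 0.2$ of their harvest) and risk death while harvesting
  (probability $m_S$ per generation);
* **generous risk-averse agents (G)** harvest moderately ($h_G = 0.5$),
  contribute everything ($c_G = 1$, or conditionally, see below) and face no
  harvesting mortality.

Each generation applies four phases in order.

**Harvesting with mortality.** The environment offers a fixed total
$e_{tot} = e \cdot N_0$ per generation, independent of the current
population size, so the per-capita offer is $e_t = e_{tot}/N_t$.  Each
selfish agent first dies with probability $m_S$; each survivor of phenotype
$p$ harvests $r_i = \min(h_p\, e_t,\ e_{max})$.

**Public goods game.** Participants place $c_{p_i} r_i$ into a communal
pot.  The community cost of anti-social behaviour removes
$(\lambda/100)$ resource units per selfish participant (the pot is floored
at zero), the remaining pot $C_t$ is multiplied by $\rho = 1.5$ and shared
equally, so individual fitness is

$$f_i = \frac{C_t\,\rho}{N_t} + r_i\,(1 - c_{p_i}) - \alpha\,[p_i = S],$$

with the individual cost $\alpha$ active only in that variant.  Fitness may
be negative; it then simply yields no offspring.

**Reproduction.** A parent with fitness $f$ dies and leaves

$$n_i = \begin{cases} 0 & f \le s\\
\left\lceil \frac{o}{M - s}(f - s)\right\rceil & s < f < M\\
o & f \ge M \end{cases}$$

offspring, where $s = 1$ is the survival threshold, $o = 10$ the maximum
brood and $M = s\,o + s$.  Offspring phenotypes are drawn independently
from the parent's personal transmission matrix, built from three heritable
components — $\phi$ (population baseline propensity to produce selfish
offspring), $\gamma$ (selfish-parent effect) and $\omega$ (generous-parent
effect):

$$\varphi_{S,S} = \phi + \gamma, \qquad \varphi_{G,S} = \phi - \omega,$$

with $\varphi_{S,G}$ and $\varphi_{G,G}$ their complements.  At the
defaults $(\phi, \gamma, \omega) = (0.1, 0.01, 0.01)$ a generous parent
produces a generous child with probability $0.91$ and a selfish parent a
selfish child with probability $0.11$.  Offspring copy the parental
components verbatim.

**Mutation.** At the start of every generation each agent's components
receive independent zero-mean Gaussian perturbations (variances
$\sigma^2_\phi = \sigma^2_\gamma = \sigma^2_\omega = 0.01$), then are
clipped: $\phi$ into $[0,1]$ first, then $\gamma$ into $[0, 1-\phi]$ and
$\omega$ into $[0, \phi]$ against the clipped $\phi$.  This order keeps all
four transmission rates inside $[0,1]$ by construction.

Although fitness does not depend on the components directly, they are under
selection through grandchildren: a parent whose components produce
offspring of the currently fitter phenotype has more grandoffspring, so the
population-mean $\phi$ tracks whichever phenotype the environment favours.

## Variants

* **Conditional cooperation** — generous agents contribute everything in
  generation 0 and thereafter the mean contribution rate of the previous
  generation's participants.  Note the only fixed point of this update is
  the selfish rate $c_S$: once generous contributions have relaxed to it
  the two phenotypes differ only through harvest rates and mortality.
* **Individual cost** — selfish agents pay a flat $\alpha = 0.1$ after
  redistribution (an ostracism/punishment proxy).
* **Perfect transmission** — offspring always express the parental
  phenotype.
* **No mutation** — the transmission components stay at their initial
  values.

## Parameters

| name | meaning | default | units |
|---|---|---|---|
| `N0` | initial population size | 250 | agents |
| `T` | generations per realization | 10^4 | — |
| `I` | realizations per ensemble | 100 | — |
| `e` | environmental offer (4.5 abundant, 1.2 scarce) | 4.5 | units/agent |
| `e_max` | per-agent harvest cap | 4.5 | units |
| `rho` | pot multiplier | 1.5 | — |
| `lam` | community cost level | 0 | % (of one unit per selfish agent) |
| `S0` | initial selfish fraction | 0.10 | — |
| `m_S` | selfish harvesting mortality | 0.25 | probability |
| `o`, `s` | max offspring, survival threshold | 10, 1 | —, units |
| `phi0, gamma0, omega0` | initial transmission components | 0.1, 0.01, 0.01 | probability |
| `sigma2_*` | mutation variances | 0.01 | — |
| `alpha` | individual cost (variant) | 0.1 | units |

The community cost is stated in the source model only as "proportional to
the number of selfish agents"; this package deducts $(\lambda/100)$
resource units per selfish participant from the pot before multiplication,
a convention that is dimensionally consistent with the survival threshold
of one unit and reproduces the qualitative ordering (larger $\lambda$,
smaller surviving community).  The proportionality constant is a declared
convention, not a fitted quantity.

## Design choices on under-determined points

* **Initial composition** is the deterministic count
  $\mathrm{round}(S_0 N_0)$ (25 selfish agents at the defaults) rather than
  per-agent Bernoulli draws, removing initial-composition variance the
  model does not call for.
* **Offer divisor**: mortality strikes before harvesting, but $e_t$ uses
  the head-count at the start of the generation, so the risky deaths do
  not enrich the survivors within the same generation.
* **Cap on the realized harvest**: $r = \min(h_p e_t, e_{max})$, not
  $h_p \min(e_t, e_{max})$ — the cap limits what an agent can take home.
* **Payout divisor and the conditional average** count the public-goods
  participants (post-mortality): only participants receive redistribution
  and only they have a defined contribution rate.
* **Mutation timing**: components mutate once per generation, at the start
  of the generation in which the agent reproduces — equivalent to
  "inherit, then mutate".
* **No epsilon nudging**: the ceiling in the offspring rule is the exact
  mathematical ceiling of the floating-point value.

## Reproducibility

Every realization runs on one R random stream seeded by an integer derived
from the master seed through an affine counter scheme
(`realization_seeds()`), and draws occur in a fixed order within a
generation: mutation noise ($\phi$, then $\gamma$, then $\omega$, each over
agents in stable order), mortality uniforms, offspring-phenotype uniforms.
A `(configuration, seed)` pair therefore determines every trajectory bit
for bit, and trajectory CSVs are written at full precision so stored runs
re-summarize identically.

## What the simulations emulate — and what they do not

The simulation *is* the study system: there is no external data.  Ensembles
emulate the published study conditions (250 founding agents, 10% selfish,
Table-like defaults above) under independent seeds.  Equilibrium statistics
average the final 10% of generations within each surviving realization and
then across surviving realizations; extinct realizations drop out of
per-generation means from their extinction generation onward.  The
equilibrium window is configurable; all tracked quantities are stationary
well before generation 1000 at the defaults, which the test suite exploits
by using horizons of 1500–4000 generations and 10–20 realizations instead
of 10^4 generations and 100 realizations.  Passing tests demonstrate
internal consistency and agreement with the published ensemble statistics
at Monte-Carlo precision; they say nothing about real human communities —
the model is a deliberately minimal caricature of selfishness and risk
preference.

## Known limitations

* **Zero-mortality extinction.** The source model reports that without
  selfish harvesting mortality the population overshoots and collapses.
  Under the equations as published this cannot happen: with $\lambda = 0$
  next generation's size $\sum_i \lceil f_i - s\rceil$ is strictly below
  $\sum_i f_i$, and $\sum_i f_i = e_{tot}\,\bar u(x)$ (with $\bar u$ the
  composition-weighted per-unit-offer fitness) is strictly below
  $e_{tot}\,u_S(x')$ for every composition pair $x, x'$ — exactly the
  population size at which the fitter class reaches the survival
  threshold.  Every term is linear in $e_t$, so the collapse region is
  unreachable: simulated zero-mortality populations settle into a
  persistent boom-bust band instead of dying.  The extinction-related
  checks in the acceptance suite are therefore expected to fail, and the
  acceptance script reports the extinction generation censored at the run
  horizon.  Alternative readings (survival threshold applied to the
  gathered amount; nearest-integer rounding of the offspring rule) were
  each tested and break other published regimes (instant scarce-environment
  extinction, loss of the conditional-cooperation survival and majority
  structure), so the printed equations are implemented literally.
* **Conditional cooperation at moderate mortality.** Because the
  conditional contribution rule relaxes to the selfish rate, the two
  phenotypes become nearly fitness-neutral and the ensemble settles near an
  even split at $m_S = 0.25$, rather than the published selfish majority.
  The generous majority at $m_S = 0.5$ does reproduce.
* **Drift levels of $\gamma$ and $\omega$.** With the clipping bounds
  above, $\gamma$ equilibrates slightly above the published
  "approximately zero" level and $\omega$ (hence $\varphi_{G,G}$) slightly
  above the published range, because both perform mutation-selection drift
  on intervals whose width is set by $\phi$.  Clipping instead to the
  weaker constraint that all four transmission rates lie in $[0,1]$ (which
  admits negative $\gamma$, $\omega$) matches those two statistics but
  degrades several others, and was rejected.
* **Community cost at $\lambda = 100$.** Selfish agents can subsist on
  retained harvest alone, so the harshest community-cost cell survives
  here whereas the source reports extinction at $m_S = 0.5$,
  $\lambda = 100$; the chosen cost constant affects this single cell only.

## A worked example

```{r example, eval = FALSE}
cfg <- pgg_config(m_S = 0.25, lam = 0, T = 2000L)
ens <- run_ensemble(cfg, n_realizations = 20, master_seed = 1)
summary(ens)          # equilibrium composition, components, extinctions
plot(ens)             # mean population size, composition, transmission rates

# mortality-by-cost equilibrium map
sw <- pgg_sweep(cfg, m_S = c(0, 0.25, 0.5), lam = c(0, 50, 100),
                n_realizations = 20, master_seed = 1)
plot(sw)
```
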