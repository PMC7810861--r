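---
title: "Modelling the gene regulatory network of direct neuronal reprogramming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the gene regulatory network of direct neuronal reprogramming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(grnconv)
```

## The biological system and the model

Direct reprogramming converts adult dermal fibroblasts into induced
neurons without a pluripotent intermediate.  The conversion decision is
thought to be governed by a small regulatory circuit built from the
splicing regulators PTB and nPTB, the neuronal microRNAs miR-124 and
miR-9/9* (aggregated here as the node `miRs`), the REST repressor complex
(REST + SCP1, aggregated as `RESTc`), and the proneural factor Ascl1.
`grnconv` models the mRNA-level dynamics of these five factors with
thermodynamic (Shea--Ackers) rate laws.

Promoter activity is the equilibrium probability that the regulatory
region is occupied by an activator:

$$SA(X) = \frac{\beta_X + \sum_{T \in act'} ([T]/k_{T,X})^{h_{T,X}}}
{1 + \beta_X + \sum_{act'} ([T]/k_{T,X})^{h_{T,X}}
  + \sum_{inh'} ([T]/k_{T,X})^{h_{T,X}}},$$

and each node follows $d[X]/dt = \alpha_X\, SA(X) - \delta_X [X]$.
Regulators outside the network are folded into the constant background
$\beta_X$ by a change of variables; for a node with no in-network
activator the background is redundant too and the activity reduces to
$1/(1+\sum_{inh'}([T]/k)^h)$.  In this package a node carries a
$\beta_X$ exactly when it has at least one non-constitutive activator
(network edge or activating external input); this rule reproduces the
published equation forms for both the literature network (β on miRs and
RESTc) and the nPTB→PTB variant (additionally β on PTB), and extends
consistently to any variant topology.

Two experimental manipulations enter as constant external inputs rather
than state variables, because the delivered factors sit far above the
endogenous scale (viral expression is at least $10^5\times$ the
fibroblast baseline): shRNA knockdown of REST is a constant inhibitor
$\beta_{\mathrm{RESTi}}$ in the denominator of $SA(\mathrm{RESTc})$, and
viral Ascl1 a constant activator $\beta_{\mathrm{vAscl1}}$ in the
numerator and denominator of $SA(\mathrm{miRs})$.  The three-stage
protocol toggles them: fibroblast (both off, a 72 h stability window),
REST knockdown (72 h, RESTi only), conversion (both on; 21 days
observed, the first 5 days fitted).

### Units and normalisation

Concentrations are relative mRNA levels with the fibroblast baseline at
1; endogenous Ascl1, undetected in fibroblasts, is expressed in units of
the qPCR detection limit.  Time is in hours; $\alpha$ has units of
concentration/hour, $\delta$ 1/hour (half-life $\ln 2/\delta$), $k$
concentration, and $h$, $\beta$ are dimensionless.  Hill exponents are
capped at 4.

## Deterministic and stochastic simulation

The production integrator is classic fixed-step RK4 with a 0.05 h step
(`integrate_stage()`, `run_protocol()`); 0.05 h divides every data
anchor (8 h, 1–5, 7, 14, 21 days) so no interpolation is ever needed.
Concentrations are clamped at zero with a clamp counter on the
trajectory.  An adaptive-step reference integrator (deSolve) is used in
the test suite only, as an independent cross-check.

Single-cell heterogeneity is simulated with the Gillespie direct method
on a rescaled reaction system (`gillespie_run()`): each node has a
production channel (jump $+\eta$, propensity $\alpha\,SA/\eta$) and a
decay channel (jump $-\eta$, propensity $\delta [X]/\eta$), so the
expected drift equals the deterministic right-hand side identically
while the variance scales with the granularity $\eta$.  The default base
granularity is 0.1; PTB and RESTc operate near relative concentration 1
and fit with much faster turnover than the other factors, so their
granularity carries two extra factors of 1/5 (effective $\eta = 0.004$;
nPTB, miRs and Ascl1 stay at 0.1).  Activities are recomputed after
every event.  The random stream is R's Mersenne-Twister, so a seed fixes
an ensemble bit-for-bit; ensembles default to 50 runs of 14 days.

## Parameter fitting

`grn_fit()` estimates all free constants by maximising
$-(SSE + R_1 + R_2)$ with a real-valued genetic algorithm:

* **SSE** compares simulated curves with the median of the three
  replicates at six anchors per factor: the REST-knockdown endpoint
  (72 h) and conversion 8 h, 1, 2, 3, 5 days.  The fibroblast stage
  contributes no error term.  miRs is bound to the miR-124 series and
  RESTc to REST (configurable via the dataset's binding).
* **$R_1$** penalises curvature, $\lambda \sum_X \int_0^{5d} |f''_X|dt$,
  with central finite differences on the RK4 grid (endpoint values
  replicated) and trapezoid quadrature; it suppresses the erratic
  oscillation a pure SSE fit adopts.
* **$R_2$** enforces that fibroblasts do not spontaneously convert:
  $\mu \sum_X \int_0^{3d} |f'_X| dt$ over the input-free fibroblast
  stage, the derivative being the model right-hand side along the
  trajectory.

Defaults $\lambda = \mu = 1/20$.  The GA uses a population of 100,
uniform crossover (per-gene 1/2 exchange between tournament-selected
parents), and a three-component multiplicative mutation
$m(2/n, 1.01)\times m(2/3n, 1.05)\times m(1/5n, 1.5)$: with probability
$p$ a gene is multiplied by a log-normal factor with geometric standard
deviation $\sigma$.  We read the $\sigma$ values 1.01/1.05/1.5 as
geometric standard deviations (≈ ±1%, ±5%, ±50% moves) — the classic
fine/medium/coarse cascade; reading them as standard deviations of the
log would make the first two components indistinguishable and deprive
the algorithm of any fine-tuning move, and in our tests the separable
toy objective then stalls two orders of magnitude short of its optimum.
Hill genes are stored unbounded and decoded through
$h = 4h'/(1+h')$, capping cooperativity at 4.  Where the algorithm's
details are genuinely open we use the smallest standard choices that
keep the best-ever fitness monotone: tournament selection, single-elite
carryover, random pairing.  Selection pressure (tournament size) and the
generation budget are exposed in `fit_config()`; desk-scale defaults are
population 100 and 150 generations.

Initial states: fibroblast and knockdown stages start at the measured
baseline (1, 1, 1, 1; Ascl1 at 0); the conversion stage starts from the
observed day-3 post-knockdown medians (policy `"observed"`, the default,
consistent with the knockdown-endpoint error term), with `"carry"` and
explicit vectors available.

More complex topologies can be seeded from fits of simpler ones
(`embed_params()`): added edges are neutralised with a large
dissociation constant, and a node that thereby gains a background term
has the reduction change of variables applied exactly in reverse, so
the embedded genome reproduces the simpler model's rate laws.

## Topology variants and model comparison

`enumerate_single_additions()` builds all single-interaction additions
among the four active nodes (12 for the literature base, after
excluding self-interactions and ordered pairs that already carry an
edge); `table2_variants()` builds the named two-interaction variants;
`variant_family()` adds the optional miRs→Ascl1 activation and the
experimentally observed PTB/nPTB self-inhibition block (the only path
by which self-edges are admitted).  `compare_models()` fits each
variant with independent restarts and ranks raw best fitness — no
complexity penalty, mirroring how the comparison is usually presented;
the generic advantage of extra free parameters is judged by comparing
against the many additions that do not help.

## Perturbation scenarios

`scenario_table()` runs the canonical eight-scenario grid (fibroblast,
OX Ascl1, OX miRs, KD REST, OX Ascl1 + KD REST, OX Ascl1 + OX REST,
OX Ascl1 + OX PTB, KD PTB).  Overexpression multiplies the factor's
transcription coefficient by 5, knockdown by 1/5; viral Ascl1 and REST
knockdown act through the dedicated input toggles.  A stochastic run
"converts" when endogenous Ascl1 reaches 1 at any time (≥ semantics,
with a strict mode; viral Ascl1 is a parameter and is never counted),
and a scenario converts when at least 1 of 50 runs does.  The combined
OX Ascl1 + KD REST row is flagged "Yes+" when its efficiency strictly
exceeds OX Ascl1 alone.  `deep_ptb_kd_probe()` repeats the PTB
knockdown at a 1/5000 multiplier with and without reducing the
constitutive RESTc background by 1/5 — the dissection-level explanation
for why PTB knockdown alone can fail to convert.  Scenario application
is guarded against accidental double application (multipliers would
compose).

## Influence dissection

`arrow_lengths()` decomposes a node's instantaneous transcription rate
into regulator arrows: $L_{act} = \Sigma_{act}/(1+\Sigma_{act})$ is the
fraction of the maximal rate realised if no inhibitor were present, and
$L_{inh}$ is defined so that $L_{act} - L_{inh} = SA(X)$ exactly.
Constitutive backgrounds and active external inputs appear as named
pseudo-regulators ("constitutive", "RESTi", "vAscl1"); sublengths are
proportional to each term $([T]/k)^h$; a decay arrow of length
$(\delta_X/\alpha_X)[X]$ completes the picture so the net arrow sum is
the rate of change in units of $\alpha_X$.  For reduced-form nodes the
constitutive activation is saturated and we render $L_{act}=1$ with
$L_{inh} = \Sigma_{inh}/(1+\Sigma_{inh})$ — the $\Sigma_{act}\to\infty$
limit of the general formulas, preserving the identity.

## The synthetic-data generator

No quantitative expression series is published for this system, so the
package generates its own study-structured data
(`make_paper_like_truth()`, `generate_dataset()`): a ground-truth model,
the three-stage protocol, the canonical ten anchors (baseline, day-3
knockdown, conversion 8 h–21 d), triplicates under multiplicative
log-normal noise (qPCR fold changes are log-scale; σ = 0.1 by default),
aggregate shadows (miR-9 jittered from the miRs node, SCP1 from RESTc,
correlating with their primaries above 0.9), and optionally the viral
plateau series.

The generating truth is drawn from a prior centred on a regime
constructed once by linear-response design to show the data's
qualitative signatures:

* an exactly steady fibroblast stage — transcription coefficients are
  solved from $\alpha = \delta [X]_0 / SA(X_0)$ at the baseline;
* a visible REST depression after knockdown without premature Ascl1
  induction;
* damped fluctuations early in conversion.  The PTB/nPTB mutual
  antagonism with the nPTB→PTB activation is the circuit's only
  negative feedback loop; its ringing quality factor is set by the loop
  gains (high cooperativity, dissociation constants near the operating
  point) and is invariant to the loop's overall timescale, so the loop
  nodes are drawn slow (δ ≈ 0.05/h) while miRs and RESTc respond fast —
  the oscillation then persists on the day timescale where the sampling
  anchors sit, instead of vanishing inside the first hours;
* eventual endogenous Ascl1 induction past the detection threshold.

Candidates are log-normal jitter (15%) around that centre and are
screened by simulation; the literature variant (no negative loop, hence
no oscillation requirement) is supported as a negative control.  What
passing tests on such data show is that the pipeline recovers
trajectories and discriminates topologies when the data actually carry
the negative-feedback signature at the anchor resolution; they cannot
show anything about biological correctness of the published parameter
values, about qPCR noise structure beyond multiplicative log-normality,
or about factors outside the five-node circuit.

## Numerical choices and limitations

* RK4 at 0.05 h is the integration contract; the final partial step is
  taken when a duration is not a step multiple, and anchors always lie
  on grid points.  Step-halving changes trajectories by < 1e-6
  relative.
* Negative excursions are clamped at zero and counted; the clamp count
  is exposed on trajectories.
* Quadratures are trapezoidal on the integration grid; second
  derivatives by central differences with endpoint replication.
* A genome whose simulation diverges receives a large negative sentinel
  fitness rather than an error, keeping GA generations intact.
* Gillespie initial states are snapped to multiples of each node's
  granularity; frozen states (all propensities zero) let the remaining
  time elapse.
* Problem sizes used in the shipped tests are desk-scale choices:
  recovery runs use a population of 100 for up to 300 generations
  (staged: the literature model first, the richer variant seeded from
  its embedded fit); comparative fits use 3 restarts per variant at a
  reduced generation budget; scenario grids use 50 runs × 14 days.
* On truths in the oscillatory regime the fitting objective is
  multimodal: desk-scale GA runs typically lock onto a competing
  phase-locked basin with anchor deviations around ten percent of the
  measurement scale, and only tighten slowly as the generation budget
  grows.  The shipped recovery test measures exactly this, and the
  corresponding check is expected to report deviations above its 5%
  bound at desk scale; populations initialised near the generating
  parameters do converge to the global basin, so the limitation is one
  of global search budget, not of the model machinery.  Topology
  discrimination is unaffected — the literature network cannot
  represent the non-monotone anchors at all, and its best fitness stays
  well below the negative-feedback variant's at every budget tried.
* SBML export writes one rate rule per species (MathML generated from
  the model structure) plus a package annotation carrying the signed
  edge list; import reconstructs a model from that annotation and
  refuses foreign files with constructs outside this dialect, naming
  them.  Stochastic channels are reconstructed from the rate law, not
  stored.

## A worked example

```{r example, eval = FALSE}
library(grnconv)

# ground truth and synthetic replicated dataset
truth <- make_paper_like_truth("nptb_ptb", seed = 42)
ds <- generate_dataset(truth$topology, truth$params, sigma = 0.1, seed = 1)

# fit the nPTB -> PTB topology to the data
fit <- grn_fit(ds, topology = truth$topology,
               config = fit_config(pop_size = 100, generations = 150,
                                   tournament = 8, elite = 4, seed = 7))
summary(fit)
plot(fit)

# perturbation grid and influence dissection on the fitted model
tab <- scenario_table(fit, seed = 1)
conv <- predict(fit, canonical_protocol())$conversion
prof <- dissect_trajectory(conv, fit$topology, fit$params, every = 40)
plot(prof, nodes = c("PTB", "RESTc"))
```
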