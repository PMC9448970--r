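---
title: "Multistate mark-recapture methods in skipmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate mark-recapture methods in skipmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipmark)
```

## The problem

Long-lived seabirds do not necessarily breed every year: a sexually mature
bird may *skip* a season (breeder → nonbreeder), and a cohort of marked adults
always contains *prebreeders* that have never yet been observed breeding.
Ignoring these states biases both survival estimates and any projection of
population growth. `skipmark` estimates, from annual encounter histories of
PIT-tagged adults at one or more colonies:

* **apparent survival** $\Phi_{s,t,c}$ — the probability that an individual in
  breeding state $s$ at colony $c$ survives the nonbreeding season between
  occasions $t$ and $t+1$ and stays in the study area (permanent emigration
  and tag failure are indistinguishable from death);
* **encounter probability** $\rho_{s,t,c}$ — the probability a live individual
  in state $s$ is detected at occasion $t$;
* **transition probability** $\psi_{s \to s',t,c}$ — the probability of moving
  between breeding states, conditional on survival.

The three live states are breeder (B), nonbreeder (N) and prebreeder (P),
plus an absorbing dead state.

## From detections to states

Raw data are dated detection records: nest inspections (which can carry
breeding evidence — eggs or chicks attended) and ground-reader pings from
fixed antennas on colony highways. An individual-season is classified:

1. **breeder** if any nest record carries breeding evidence, *or* the
   ground-reader rule passes: detections on ≥ 6 distinct days within the
   March 1 – October 31 season whose overall span (last − first) is between
   12 and 120 days inclusive. The span is computed over the whole set of
   detected days; the rule's bounds are read as inclusive. A consequence is
   that extra detections far outside an existing cluster can push the span
   past 120 days — monotonicity ("more evidence never demotes") holds only
   for detections added inside the current span, and the property test
   asserts exactly that restricted form.
2. **nonbreeder** if encountered at all and previously observed breeding;
3. **prebreeder** if encountered but never yet observed breeding;
4. **0 (not encountered)** otherwise.

Seasons with no encounter are coded 0 and handled by the detection
probability in the likelihood. We deliberately do *not* impute a nonbreeder
observation for unobserved-but-later-reobserved seasons: imputation would
force nonbreeder detection probability to 1, contradicting the clearly
state-dependent detection in this study design. The unobserved season's state
is latent and the hidden-Markov likelihood integrates over it.

Exclusion filters mirror the study design: double-marked individuals (an
input list — band histories predate the pipeline) are removed entirely, as is
any individual observed breeding at more than one colony. Individuals merely
*detected* at two colonies are assigned their modal colony under the default
policy (`multi_colony = "breeding"`), or removed under `"any"`.

## The likelihood

Conditioning on each individual's first capture (occasion and observed
state), the probability of an encounter history is a forward recursion over
the latent state vector $\alpha \in \mathbb{R}^4$:

$$\alpha_{t+1} = (\alpha_t^\top M_{t,c}) \odot w_{t+1}, \qquad
  M_{t,c}[s, \cdot] = \big(\Phi_s \psi_{s\to B}, \Phi_s \psi_{s\to N},
  \Phi_s \psi_{s\to P}, 1 - \Phi_s\big)$$

with the dead row $(0,0,0,1)$ and the observation weight $w$ equal to
$\rho_{s}$ on the matching latent state when the bird was seen in state $s$
(observed states are assumed recorded without misclassification), and
$(1-\rho_B, 1-\rho_N, 1-\rho_P, 1)$ when unseen. The history probability is
$\sum_s \alpha_T$; identical (colony, pattern) histories are collapsed with
multiplicities. The test suite checks this recursion against an explicit
enumeration of all latent state paths to $10^{-10}$, and checks that the
probabilities of all possible observation histories given a first capture sum
to one.

**Links.** $\Phi$ and $\rho$ are logit-linear. Each $\psi$ row is a
multinomial logit with "stay" as the reference category; because the
impossible transitions $\psi(P \to N)$, $\psi(N \to P)$ and $\psi(B \to P)$
are structural zeros, each origin state has exactly one permitted non-stay
destination (B→N, N→B, P→B) and the row reduces to a single movement logit.
Row sums to one and the structural zeros hold by construction.

**Design.** Model structures are R formulas over the factors `state`, `time`,
`colony` and the standardized interval covariates `sardine`, `anchovy`,
`combined`. Each parameter class has a cell grid (state × interval/occasion ×
colony); `model.matrix` realizes the formula on that grid. Fixed cells —
parameters known from the marking design, e.g. nonbreeder/prebreeder survival,
transition and recapture around occasions where no such birds had yet been
marked — are masked out of estimation, reported at their fixed value with
SE 0, and excluded from the parameter count $K$ (columns identified only by
fixed cells are dropped). This mirrors how fixed real parameters are counted
in mainstream capture-recapture software, which matters because $K$ enters
QAICc.

**Covariates.** Survival over the nonbreeding season between breeding
seasons $y$ and $y+1$ is paired with the November-$y$ spawner-biomass survey.
Covariates are z-scored over the supplied survey years before entering the
linear predictor (`combined` is sardine + anchovy summed *before*
standardization). Slopes are therefore on the standardized scale; sign
comparisons are unaffected, and the scaling is stored with the fit so
predictions accept raw tonnes.

## Estimation

`fit_msmr()` maximizes the log-likelihood with BFGS using numerical
gradients, from `n_starts` seeded starts (default 5; the first is the neutral
point $\beta = 0$, the rest are jittered). Multi-start matters: the surface
has a spurious mode with breeder detection pushed to 1 and inflated skipping,
which a lone neutral start occasionally reaches; the true mode has better
likelihood and multiple starts recover it. Convergence uses a relative
objective tolerance of $10^{-10}$; linear predictors are clipped at ±35
before the inverse link purely to avoid overflow.

The covariance is the inverse numerical Hessian. If the Hessian is rank
deficient — boundary estimates, or intrinsically confounded terminal
parameters such as the last-interval survival × last-occasion detection
product of a fully time-dependent model — it is pseudo-inverted and every
cell loading on a null direction is flagged `inestimable` rather than
silently dropped. Real-scale SEs use the delta method on the logit scale
($\mathrm{se}_p = p(1-p)\,\mathrm{se}_\eta$); 95% intervals are computed on
the logit scale and back-transformed, so they respect $[0,1]$. Real-scale
two-SE coverage is slightly below nominal in finite samples along the
correlated detection/transition ridge (the recovery tests print the measured
per-parameter coverage); this is a property of Wald intervals, not of the
optimizer or the Hessian, both of which the suite cross-checks independently.

## Goodness of fit, overdispersion and model selection

The omnibus goodness-of-fit test for the general (state × time × colony)
model is assembled from contingency-table components in the spirit of the
JMV omnibus test, computed per colony and summed:

* **Test3G.SR** — per occasion and state, newly marked vs previously seen
  animals against ever re-encountered or not (transience signal);
* **Test3G.Sm** — among previously seen animals re-encountered later,
  previous encounter immediately before vs earlier against next encounter
  immediately after vs later (memory signal);
* **TestM.ITEC / TestM.LTEC** — animals known alive at $t+1$ (resp. missed at
  $t+1$, known alive at $t+2$), state at $t$ against detected or not
  (immediate / longer-term trap effects on encounter).

Cells are pooled by repeatedly merging the column holding the smallest
expected count below 2 into its nearest neighbour (then rows), decrementing
the degrees of freedom; degenerate tables contribute 0 df, never NaN. The
exact stratification and pooling used by the original software for this kind
of test is not published in enough detail to replicate digit-for-digit, so
the components here are documented analogs: the omnibus statistic, its df and
their ratio are auditable from the per-table output.

$\hat c = \chi^2/\mathrm{df}$ of the omnibus test estimated **once** from the
general model and applied to every candidate;
$\mathrm{QAICc} = -2\ln L/\hat c + 2K + 2K(K+1)/(\mathrm{ESS}-K-1)$.
The effective sample size is the number of release events — each occasion
before the last at which an individual is encountered alive contributes one
(the common convention in mark-recapture software; the source analysis does
not state its choice). Selection is stepwise: encounter structures first, the
winner carried forward to survival, then transition, the other classes held
at the general (or already-selected) structure. Within ΔQAICc < 2 the model
with fewest parameters wins; ties on $K$ fall back to the lower QAICc.
p-values are reported but never used for selection.

## The synthetic world

`sim_config()` describes a truth-known world mirroring the study design:
eight seasons (2013–2020), two colonies, only breeders marked in season 1
and mixed cohorts afterwards (with no nonbreeding birds marked at the first
colony in season 2, which is what motivates the extra fixed parameters).
Within an interval an individual first survives, then transitions, and is
detected at the following occasion — the standard
conditional-on-first-capture ordering. Default true parameters sit near
field-realistic constant estimates: $\Phi \approx 0.75$–$0.80$,
$\rho_B = 0.9$, $\rho_{N/P} \approx 0.5$, skipping
$\psi_{B \to N} = 0.22 / 0.10$ by colony, return
$\psi_{N \to B} = 0.66 / 0.69$.

Detection records are emitted at two levels. `simulate_histories()` draws
observations directly (observation = latent state with probability
$\rho$) for fast fitting tests. `emit_detections()` produces dated records:
a nest record with breeding evidence per breeder-season with probability
`nest_check_rate`, and Poisson ground-reader pings per state. Breeder records
are dated uniformly within a 110-day breeding-attempt window placed uniformly
inside the season, not across the whole 8-month season: breeders commute to
the colony for the duration of an attempt, and uniform dating over 245 days
would make a typical 20-ping season span far beyond the rule's 120-day
maximum, i.e. the detection process and the classification rule would be
mutually inconsistent. Nonbreeder and prebreeder pings stay uniform over the
season; their intensity is a free design choice (no published value exists).

What the generator does **not** emulate: tag loss or failure (subsumed in
apparent survival), movement between colonies, chick/fledgling stages,
re-marking, within-season breeding failure dynamics, and observer-side state
misclassification. On that last point, note that `simulate_histories()` emits
the *latent* state as the observed code, while real observers code a bird
that bred undetected as a prebreeder; the record-level generator plus the
classifier reproduce that observer behaviour, the direct generator
deliberately produces model-consistent data. A green recovery test therefore
establishes that the estimator inverts its own generative model — not that
the classification rules are free of misclassification on real data.

## Numerical and edge-case choices

* Convergence: relative objective tolerance $10^{-10}$ (tighter than the
  $10^{-8}$ target); multi-start seeds fixed by configuration.
* History probabilities are floored at $10^{-300}$ inside the log only to
  keep impossible-history likelihoods at a large finite penalty.
* Empty record sets classify as 0 (not an error); empty ping sets fail the
  ground-reader rule (not an error); df = 0 makes $\hat c$ an explicit error.
* $\hat c < 1$ is reported as-is with a note; the pipeline floors it at 1 by
  default (`chat_floor`), a documented convention.
* Non-converged candidates are excluded from selection with a logged reason;
  a stage in which every candidate fails aborts the pipeline with the stage
  name.
* The `.inp` dialect is bit-exact and round-trips through the CSV mirror;
  fits are invariant to individual order and input dialect (tested).

## Known limitations

* Real-scale Wald intervals undercover slightly in finite samples for
  strongly correlated detection/transition parameters (measured and printed
  by the recovery tests).
* The GOF components are documented analogs of the published contingency
  tests, not a digit-for-digit replication of any particular implementation;
  $\hat c$ should be read accordingly.
* No state-uncertainty (multievent) extension: observed states are taken at
  face value.
* Reproducing the published study-scale numbers requires the deposited
  encounter data (Dryad `doi:10.5061/dryad.0rxwdbs3z`), a documented manual
  download; see `?reproduce_study_analysis`.
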