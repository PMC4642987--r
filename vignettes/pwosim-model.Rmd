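---
title: "The pwosim model: trust-gated harvesting decisions on a parcel grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pwosim model: trust-gated harvesting decisions on a parcel grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwosim)
```

## The system being modelled

Non-corporate private woodland owners control a large share of the forested
landscape in the eastern United States, and the timber supply and ecological
condition of that landscape emerge from thousands of individually made
harvesting decisions. Those decisions are not purely economic: they are
shaped by who the owner talks to — professional foresters, conservation-
trained "peer leaders", and neighbours — and by how much the owner trusts
what each of those sources says.

`pwosim` implements a stylised, spatially explicit agent-based model of this
system. The landscape is a rectangular grid of forest parcels, one owner per
parcel. Two kinds of mobile influencer visit owners each year: foresters
(many visits, able to recommend a harvest) and peer leaders (few visits,
advocates for sustainable management and for foresters). Owners additionally
gossip among themselves. Trust is the central state variable: every
influence attempt succeeds only with probability equal to the owner's
current trust in that source, and trust itself is updated by the same
interactions.

## Agents and state

Each parcel carries its owner's demographics (drawn once at initialization
from survey-derived distributions, see below), the stand state, and the
social state:

* `forest_age`, `forest_type` determine **harvestability**: a stand is ready
  for pre-commercial thinning from age 15, and mature at age 40 (softwood)
  or 60 (hardwood). Harvesting resets `forest_age` to 0.
* `sustainability` (0/1) is the owner's disposition: a sustainable-inclined
  owner only cuts mature stands; an unsustainable-inclined owner will also
  cut a pre-commercial stand, risking conversion to an undesirable species
  mix. Influencers can switch this value to 1; nothing switches it back.
* `forester_trust` and `peer_trust` are probabilities in [0, 1].
* `psychdist` (psychological distance) is stored for future use and read by
  nothing, mirroring the state table of the source model.

## The annual schedule

Each tick is one year and runs in a fixed order (patches row-major,
influencers in roster order), which makes a run bit-reproducible from its
seed:

1. **Reset and ageing.** Harvest flags clear; owners age one year (at 100 the
   parcel passes to a new owner, redrawing the age — optionally the whole
   demographic profile via `turnover_redraws_all`); stands grow one year and
   readiness is recomputed.
2. **Pre-interaction decision.** The logistic score
   $H = -3.065 + 0.001A - 0.30L + 0.282I + 0.03\,AG + 0.01F$
   (area, residency class, harvest objective, age, family tenure) gives
   $p = 1/(1+e^{-H})$, and a uniform draw on (0.5, 1) below $p$ sets the
   year's harvest intent. The implied intent probability is
   $\max(0, 2p - 1)$: only owners whose predisposition exceeds one half can
   form intent on their own.
3. **Forester visits.** Each forester visits its fixed number of uniformly
   random parcels (with replacement). Per visit, three trust-gated steps:
   sustainability set to 1; harvest intent set if the stand is mature; trust
   moved up by U(0, 0.75) or down by U(0, 0.5) depending on whether the
   experience was positive — itself decided at probability equal to current
   trust. The asymmetric increments encode that trust is won in larger steps
   than it is lost; the expected unclamped change crosses zero at trust 0.4.
4. **Peer-leader visits.** As above, gated by peer trust: sustainability set
   to 1; peer trust moved by ±U(0, 1); forester trust *boosted* by U(0, 1)
   (peer leaders speak well of foresters; this channel never lowers trust).
   Peer leaders never create harvest intent.
5. **Opinion spread.** Every owner shares once, with a fair coin choosing
   between a uniformly random other owner anywhere and a uniformly random
   Moore-adjacent neighbour. Under the default `trust_gated` mode the
   opinion lands with probability equal to the recipient's mean trust; a
   landed positive/negative opinion moves both of the recipient's trust
   channels by ±U(0, 1); a neutral opinion moves nothing.
6. **Final decision and locking.** Intent is resolved against readiness and
   disposition (step 2 of the table above); then any trust channel that has
   stayed above 0.7 (below 0.3) for 5 consecutive ticks is permanently set
   to 1 (to 0) — attitude hardening into belief. Locked channels still gate
   influence but never move again.
7. **Recording.** Percent of parcels harvested (split exactly into
   sustainable and unsustainable cuts), percent of owners with trust > 0.5
   per channel (exactly 0.5 counts low, matching the strict definition of
   "high"), and landscape means.

## Initialization distributions

The synthetic landscape is the study population; no external data is read.
Owner demographics reproduce the moments of a landowner survey:

| field | distribution | target |
|---|---|---|
| `inct` (harvest objective, 0–5) | Poisson right-truncated at 5, rate calibrated by root-finding so the *truncated* mean is 2.66 | mean 2.66 |
| `age` | Normal(56.96, 12.68), clamped to [18, 99] | mean 56.96 |
| `lngfam` | Poisson(31.46) | mean 31.46 |
| `live` (residency 1–4) | categorical (0.38, 0.30, 0.22, 0.10) | mean 2.04 |
| `ha` (parcel area) | log-normal, moment-matched to mean 35.50 / sd 85.49, floored at 0.4 ha | mean 35.5 |

Only the mean of `live` is reported by the survey table; the categorical
probabilities are this package's declared convention (residency most
common, decreasing). Likewise the area distribution family is a choice: an
sd 2.4 times the mean demands a heavy right tail, and the log-normal is the
standard parcel-size model. Calibrating the truncated Poisson matters:
sampling Poisson(2.66) and clipping at 5 would bias the mean low by several
percent.

Stand age starts uniform on 0–60, forest type and sustainability are fair
coins, and both trust channels start uniform on (0, 1) — the survey gives
only "stochastic" for these. The 33 × 33 grid is a choice as well: with a
mean parcel of 35.5 ha it carries roughly 38,700 ha, consistent with the
"over 33 thousand ha" the model is meant to represent.

## Parameters that matter

* `n_foresters` (default 20) and `forester_visits_range` (default [50, 100]
  visits/year, the workload of a private licensed forester) control how
  often harvest recommendations and trust experiences occur. Together they
  put roughly 1500 visits/year on 1089 parcels.
* `n_peer_leaders` (default 2) with 1–5 visits/year is deliberately a weak,
  purely positive channel.
* `opinion_type` (default neutral) switches the valence of peer-to-peer
  gossip. Positive opinion spread is a strong upward force on both trust
  channels (an accepted opinion adds U(0, 1) every year), so it drives the
  landscape toward locked-high trust; negative spread symmetrically down.
* `trust_lock_high`/`low`/`window` (0.7 / 0.3 / 5) determine how quickly
  trust trajectories absorb. Because increments are large relative to the
  0.3-wide outer bands, most of the landscape reaches a locked state well
  within an 80-year run.
* `mature_age_softwood`/`hardwood`/`precommercial_age` (40 / 60 / 15) set
  the regrowth clock and hence the sustainable harvest flux an 80-year run
  can support.

The default run length is 80 ticks with a 10-tick burn-in excluded from
summaries: the first years see a pulse of cutting as the initially mature
parcels are harvested, which is not representative of the trend. Longer
horizons (the model supports any `n_ticks`, e.g. 400 years ≈ 4–5 rotations)
mainly re-run the regrowth cycle.

## The batch-experiment layer

`run_sweep()` varies exactly one of `forester_visits`, `peer_visits`,
`n_foresters`, `n_peer_leaders`, `opinion_type` across levels with
replicated runs; every run receives a distinct seed derived from the sweep's
master seed, so replicates share no random state and the whole table is
reproducible. `aggregate_sweep()` pools all rows (levels and replicates
together — the convention of a one-row-per-variable summary) into min / max
/ mean / sd, and `anova_one_way()` runs the classical fixed-effects one-way
ANOVA of a metric across levels. The per-run metric used for pooled
summaries is the final-tick value, and the headline metrics are the percent
of owners with forester trust above 0.5 and the percent of parcels
harvested in the year.

The sweep base configuration holds 20 foresters, 2 peer leaders, and
**neutral** opinion spread. Neutral, not positive, is deliberate: positive
gossip at U(0, 1) increments is strong enough to drive most of the
landscape to locked-high trust within a few decades, which contradicts the
reference behaviour the sweeps are meant to reproduce (mid-50s percent
high trust, trust declining slowly over time); in the source experiments a
positive opinion climate is the explicitly flagged special condition, not
the baseline. `variable_importance()` offers a permutation-importance
ranking (over a random-forest fit) as a transparent substitute for a
boosted-regression-tree influence analysis.

For the replication experiments shipped in `scripts/acceptance.R` the
problem sizes are 3 visit levels × 25 replicates, 21 forester levels × 10,
6 peer-leader levels × 25, and 3 opinion levels × 25, all on the full
33 × 33 grid over 80 ticks — enough replication that pooled means are
stable to well under a percentage point.

## Numerical and design choices

* **Logistic link.** The harvest-predisposition equation is introduced as a
  logistic regression, so the score is mapped through $1/(1+e^{-H})$; the
  coefficients are taken as given, not refitted.
* **Within-tick collision semantics.** Several visits (or opinions) can hit
  one parcel in one tick. They are applied strictly in arrival order; the
  implementation pre-draws every visit's random numbers in visit order and
  then sweeps occurrence rounds, which is vectorised but provably identical
  to sequential application.
* **Neighbourhood.** "Adjacent" is the Moore (8-cell) neighbourhood, the
  usual choice for opinion spreading on a lattice; edge parcels simply have
  fewer neighbours.
* **Harvest classification.** A cut executed on a mature stand is counted
  sustainable even if the owner is unsustainable-inclined — sustainability
  of a cut is treated as a property of the stand state. `classify_by_owner`
  flips to owner-based classification.
* **Ties and edges.** Trust exactly at a lock threshold does not count
  toward locking; trust exactly 0.5 is classified low; an owner at exactly
  the death age turns over; a single-parcel landscape skips opinion spread
  (no valid target).
* **Degenerate ANOVA.** Zero within-group variance with differing means
  reports F = ∞, p = 0 rather than NaN.

## What the generator does and does not emulate

The synthetic landscape reproduces the marginal distributions of owner
demographics and a plausible stand-age mosaic. It does **not** reproduce
spatial autocorrelation of parcel sizes or forest types, real road/market
access, prices, partial harvests, or any empirical social-network topology
(visits are uniformly random). Consequently, passing tests show that the
decision, trust, and scheduling machinery behaves as specified under the
declared study conditions — not that the model predicts harvest rates on
any real landscape. In particular, the annual percent of the landscape
harvested late in a run is governed almost entirely by the regrowth clock
and the rarity of spontaneous harvest intent (the logistic predisposition
exceeds 0.5 for only a small tail of owners), both of which are
under-determined by the source description; the trust metrics are the
robust outputs.

## Known limitations

* No utility or price signal; the harvest decision is purely social and
  demographic.
* Sustainability is absorbing at 1; no mechanism erodes it.
* `psychdist` is carried but unused, by design.
* Percentages are parcel counts, not area-weighted (the parcel is the
  decision unit); area weighting would need only a different aggregation.
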