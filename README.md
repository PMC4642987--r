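# pwosim

An agent-based simulation of timber-harvesting decisions by private woodland
owners (PWOs), for researchers studying how social interactions, information
flow, and trust in natural-resource professionals shape landscape-scale
forest management.

The landscape is a grid of forest parcels, one owner per parcel. Each year
every owner forms a harvest predisposition from a survey-derived logistic
score

```
H = −3.065 + 0.001·A − 0.30·L + 0.282·I + 0.03·AG + 0.01·F
p = 1 / (1 + e^−H),   intent drawn as  U(0.5, 1) < p
```

(A parcel area, L residency class, I harvest objective, AG owner age,
F family tenure). Professional foresters and conservation-trained peer
leaders then visit randomly chosen owners, and owners gossip with neighbours
or random strangers. Every influence attempt — switching an owner to a
sustainable disposition, recommending a harvest on a mature stand, or
shifting trust itself — succeeds with probability equal to the owner's
current trust in that source. Trust moves in asymmetric uniform increments
(won faster than lost for foresters), and any channel that stays above 0.7
(below 0.3) for five consecutive years locks permanently at 1 (at 0).
Harvests are resolved against stand readiness: sustainable-inclined owners
cut only mature stands, unsustainable-inclined owners also cut
pre-commercial ones. The package also ships the batch layer that produced
the model's reference analyses: one-variable parameter sweeps with
replicated seeded runs, pooled summary tables, one-way ANOVA across sweep
levels, and a permutation-importance ranking of factors.

## A worked example

```r
library(pwosim)

cfg <- pwo_config(seed = 1)       # 33x33 parcels, 20 foresters, 2 peer leaders
rec <- run_model(cfg)             # 80 annual ticks
rec[c(1, 2, 10, 40, 80), c("tick", "pct_harvested", "pct_sustainable",
                           "pct_high_forester_trust")]
#>  tick pct_harvested pct_sustainable pct_high_forester_trust
#>     1         11.20           11.11                   52.98
#>     2          4.22            4.22                   55.10
#>    10          1.47            1.38                   56.01
#>    40          1.47            1.29                   56.01
#>    80          1.74            1.47                   56.01

summarize_run(rec, burn_in = 10)[c("pct_harvested_mean", "final_pct_high_forester_trust")]
#> post-burn-in harvest mean 1.53% (sd 0.88), final trust-in-forester 56.0%
```

The first years show the pulse of cutting as initially mature parcels are
harvested; afterwards the annual cut settles at the rate the regrowth clock
supports, and a small majority of owners end up trusting foresters
(trust > 0.5). Sweeping a variable:

```r
sw <- run_sweep("n_peer_leaders", c(0, 2), 4, pwo_config(), master_seed = 42)
tapply(sw$final_pct_high_forester_trust, sw$level, mean)
#>     0     2
#> 51.95 54.84
anova_one_way(sw, "final_pct_high_forester_trust")
#> ANOVA across levels: F = 8.03, p = 0.030
```

Peer leaders only ever speak well of foresters, so a landscape without them
ends with measurably less trust in foresters.

A shell front end wraps the same functions
(`Rscript inst/cli/pwosim.R run --config cfg.yml --out out/` and
`... sweep --spec sweep.yml --out out/`); configs are flat YAML key/value
files, and every run writes a manifest of its fully resolved parameters.

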