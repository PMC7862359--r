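# herdtyper

Herd-type classification for cattle registers with self-organising maps.

## The problem

National cattle registers (such as the Irish Animal Identification and
Movement database) record every bovine's identity, sex, breed, parentage,
birth and each movement between holdings. For disease surveillance and
epidemiological modelling it is not the individual animal that matters but
the *management type* of the herd: a contract-rearing herd, a fattening
unit and a self-replacing dairy herd play very different roles in the
trading network and in pathogen spread. `herdtyper` implements a complete,
tested pipeline that turns such a register into a herd-type classification:

1. **Feature engineering** — nine herd-level variables from three
   demographic snapshots (1 January, 1 May, 1 September) and one year of
   movements: `pFemaleAnimals`, `pDairyBreed`, `pCrossBreed`,
   `pCalvedAnimals`, `pMalesBetween1and2Years`, `pAnimalsLess30Days`,
   `pOutMovesToSL`, `pOutMovesToBirthHerd`, `pInMovesToBirthHerd`.
2. **Visual rule extraction** — from-scratch self-organising maps (SOMs)
   and supervised bi-directional Kohonen (BDK) maps with component planes
   and region histograms. Training follows the classical scheme: for each
   record `z`, the best matching unit `w* = argmin_{x,y} |w_xy − z|` is
   found, then every node moves by
   `w_xy ← w_xy + α · β_xy · (z − w_xy)` with the Gaussian neighbourhood
   `β_xy = exp(−d²/(2σ²))`, and `α`, `σ` decay after each epoch.
3. **Classification** — a 13-decision tree (10 binary, 3 ternary) over the
   nine variables assigning each herd to one of **17 herd types** in six
   main groups (dairy, beef, mixed, store/rearing, fattening, trading),
   with at most 6 decisions per herd, plus threshold-sensitivity bands
   (the interval a threshold would have to move to reassign 10% of the
   herds at that decision).
4. **Synthetic register generation** — because real register extracts are
   confidential, a generator emulates the management signatures of all 17
   herd types, so the entire pipeline is testable end to end and every
   classification rule can be exercised against known truth labels.

The seed classification follows the Irish Cattle Breeding Federation
convention: a herd is a breeding enterprise iff ≥ 25% of its animals have
ever calved by 1 September; breeding herds are dairy at ≥ 70% dairy-bred
animals, beef below 30%, mixed otherwise.

## Worked example

```r
library(herdtyper)

gen <- generate_registry(herds_per_type = 10, seed = 42)
gen$registry
#> <herd_registry>
#>   animals:   15966 in 170 herds
#>   movements: 11749
#>   study year 2017; snapshots 2017-01-01, 2017-05-01, 2017-09-01

feats <- compute_features(gen$registry,
                          gen$truth$herd_id[gen$truth$role == "primary"])
feats[1, c("herd_id", "pFemaleAnimals", "pDairyBreed", "pCalvedAnimals")]
#>     herd_id pFemaleAnimals pDairyBreed pCalvedAnimals
#> 1 H01_D_001          0.949       0.897            0.5

cl <- classify_herd(build_default_tree(), feats[1, ])
cl$herd_type
#> [1] "D"
cl$path
#>   node                variable value branch
#> 1   D1          pCalvedAnimals 0.500      2
#> 2   D2             pDairyBreed 0.897      3
#> 3   D3 pMalesBetween1and2Years 0.062      1
#> 4   D4          pCalvedAnimals 0.500      1
```

The herd is a breeding enterprise (50% calved ≥ 25%), dairy (89.7% ≥ 70%),
keeps almost no male yearlings and rears its own replacements — a typical
dairy herd (`D`), reached in 4 of the maximum 6 decisions.

The full pipeline (featurize → initial classify → supervised map → tree
classify → report):

```r
report <- run_pipeline(pipeline_config(herds_per_type = 10, seed = 42))
report
#> <run_report> 170 herds classified
#>   types: BP=10 BSB=10 BSW=9 BSY=11 BSY-nR=10 D=10 DRm=10 DnR-C=10 DnR-nC=10
#>          F=10 M=10 Rdf=10 Sbf=10 Sbm=10 Sbmx=10 Sdm=10 T=10
#>   BDK resubstitution accuracy: 1.000
#>   truth-label recovery: 99.4%
```

All 17 types are recovered; the two swaps sit on the (deliberately
neighbouring) BSY/BSW yearling-share boundary. A thin command-line wrapper
over the same functions is installed at `inst/cli/herdtyper.R`
(`generate`, `featurize`, `classify`, `run`, `walkthrough` subcommands).

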