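Package: murreforage
Title: Biologging Analysis of Seabird Foraging Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for analysing biologger deployments on
    central-place foraging seabirds (thick-billed murres). Classifies
    per-fix behaviour (colony, flying, swimming, diving) with a
    multivariate hidden Markov model (Baum-Welch fitting, Viterbi
    decoding), segments deployments into foraging trips and dive bouts by
    post-dive interval, computes foraging and diving metric tables and
    activity-budget daily energy expenditure, estimates kernel utilization
    distributions with href bandwidths and Bhattacharyya affinity overlap,
    reduces metric tables by varimax-rotated principal components with
    Kaiser retention, scores nutritional biomarkers as log-ratio change,
    and ranks candidate mixed models by AICc with VIF screening and
    Nakagawa marginal and conditional R-squared. A seeded synthetic-data
    generator emulates deployments, environmental rasters and biomarker
    panels so the whole chain runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    lmerTest,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    geosphere,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'biomarkers.R'
    'config.R'
    'dimreduce.R'
    'geo.R'
    'divetrip.R'
    'energetics.R'
    'env.R'
    'hmm.R'
    'inference.R'
    'io.R'
    'murreforage-package.R'
    'simulate.R'
    'spaceuse.R'
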