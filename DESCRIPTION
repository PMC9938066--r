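Package: npodrl
Title: Reinforcement-Learning Guided Nonparametric Population
    Pharmacokinetic Model Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automates the iterative structural-model and parameter-bound
    search of nonparametric population pharmacokinetic modelling. A
    nonparametric maximum-likelihood estimator in the NPOD style (Sobol
    initialization, simplex-constrained weight optimization, cyclic
    Nelder-Mead support-point refinement) serves as the inner optimizer of
    a Markov decision process whose discrete actions widen or narrow
    parameter bounds or switch between one- and two-compartment models. A
    tabular SARSA agent with an epsilon-greedy policy learns which action
    sequences maximize the population log-likelihood. Includes analytic
    one- and two-compartment kinetics with bolus and infusion dosing, a
    synthetic-population generator with ground truth for recovery
    experiments, and a command-line interface for reproducible
    simulate/fit/train/rollout runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
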