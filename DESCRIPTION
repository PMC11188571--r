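Package: forgetq
Title: Forgetting Q-Learning Models of Reward Seeking Under Punishment Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling trial-by-trial lever-pull choice behavior in
    head-fixed rodent tasks where reward seeking carries a risk of positive
    punishment (an air-puff) or negative punishment (reward omission).
    Implements a family of seven forgetting Q-learning model variants with a
    sigmoidal choice rule, maximum-likelihood fitting with multi-restart
    bounded optimization and AIC/BIC model comparison, generative
    (posterior-predictive) simulation of choice sequences scored by RMSE,
    and a single-parameter grid-search perturbation analysis that attributes
    a behavioral change (e.g. after pharmacological inactivation) to one
    model parameter. Includes generative task environments for the air-puff
    and omission task structures and synthetic-agent data generators so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
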