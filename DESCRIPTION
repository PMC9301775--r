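Package: prosocca
Title: Computational Models of Prosocial Choice and Trait Canonical
    Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling two laboratory measures of prosocial
    behavior -- harm aversion in a money-versus-shocks trade-off task and
    effort discounting in a work-versus-rest task -- and for relating the
    derived prosociality indices (hyperaltruism and prosocial effort) to a
    battery of affective and psychiatric trait scores.  Provides softmax
    discrete-choice models fitted per participant by bounded multi-start
    maximum likelihood, performance-based quality-control exclusions,
    nonparametric behavioral statistics (Wilcoxon signed-rank, Spearman
    correlation, Fisher r-to-z comparison, repeated-measures ANOVA with
    Greenhouse-Geisser correction), canonical correlation analysis with
    sequential Wilks/Rao tests, permutation inference on Roy's largest
    root, commonality partitioning of explained variance, and a synthetic
    cohort generator with planted ground truth for end-to-end validation
    and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
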