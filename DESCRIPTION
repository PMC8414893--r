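Package: intellipheno
Title: Automated Home-Cage Behavioral Phenotyping: Simulation, Metrics and Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing IntelliCage-style automated home-cage
    behavioral phenotyping experiments. Provides a validated relational
    event-log model (visits, nosepokes, licks) with a tab-separated
    interchange format; deterministic controllers for the standard task
    battery (free/door/nosepoke adaptation, place preference and reversal,
    serial-reaction-time attention task, airpuff place avoidance and
    retention); per-animal per-day dependent-variable computation including
    adaptation pass/fail classification; a seeded stochastic mouse-agent
    simulator with genotype-dependent behavioral parameters and retained
    ground truth; and the matching statistical battery (mixed repeated-
    measures ANOVA with Mauchly sphericity assessment, Bonferroni-gated
    post hoc comparisons, and pooled two-sample t tests from raw data or
    printed summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
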