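Package: lugshift
Title: Behavioural Game Models of Minority-Language Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling language shift in modern bilingual societies
    (Basque, Irish, Welsh and the like) as the outcome of bilinguals' strategic
    language choices. Implements the Language Use Game, a 2x2 strategic-form
    game under imperfect information about interlocutor type, together with its
    replicator dynamics, the closed-form evolutionarily stable equilibrium, and
    a finite-population imitation simulator. Provides the derived predictive
    models of street use and daily use of the minority language, constrained
    nonlinear least-squares estimation from locality-level survey tables,
    pairs-bootstrap confidence bands, a local-linear nonparametric
    specification check, and a synthetic-data generator with binomial
    observation noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    KernSmooth,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
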