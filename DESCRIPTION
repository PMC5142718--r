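Package: fecundmix
Title: Mixture Cohort-Depletion Models of Fecundability and Early Embryo Mortality Bounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits finite-mixture cohort-depletion models to per-cycle aggregate
    counts from prospective human conception studies monitored with hCG.
    A starting cohort of couples is modelled as a two-point (optionally one- or
    three-point) mixture of fertile and sub-fertile sub-cohorts, each with its
    own per-cycle probability of an hCG-detected conception; hCG pregnancies
    progress to clinical recognition with a further conditional probability.
    Parameters are estimated on the base-10 logit scale by minimising an
    extended-least-squares objective with a power-of-the-mean residual
    variance model, with inverse-Hessian standard errors and Wald intervals.
    Nested model variants are compared with likelihood-ratio tests. The
    package also implements the stage-wise reproductive-success probability
    chain (sperm-ovum co-localisation, fertilisation, implantation, clinical
    recognition, live birth) used to bound early embryo mortality under
    explicit scenario assumptions, and a seeded individual-level simulator of
    prospective conception studies so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
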