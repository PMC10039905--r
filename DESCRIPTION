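Package: hehsim
Title: Simulation and Analysis of High-Hyperdiploid Karyotype Evolution
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time population simulator of aneuploidy initiation and
    clonal selection in high-hyperdiploid (HeH) childhood acute lymphoblastic
    leukaemia, covering five initiation mechanisms (sequential gains in a
    diploid or tetraploid background, tripolar mitoses of diploid or
    tetraploid cells, and mitotic catastrophe by complete cohesion loss)
    with homologue-resolved karyotypes, a survival/proliferation score with
    a beta-law aneuploidy penalty, and a uniparental-isodisomy stopping rule.
    Companion analysis tools compute cohort-level karyotype statistics
    (copy-state spectra, tetrasomy 2:2/3:1 typing, UPID/disomy ratios,
    subclonality binomial tests), RMSE model comparison against cohort
    profiles, mutation timing of SNVs on gained chromosomes (BTRI versus
    B/ATRI classes from variant allele fractions), and clone bookkeeping on
    single-cell whole-chromosome copy-number matrices. Synthetic-data
    generators emulate cohort tables, variant tables, and single-cell
    matrices so that every analysis stage can be exercised without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
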