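Package: kscutotype
Title: Skin Cutotype and Aging-Group Analysis from Biophysical and Microbiome Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis framework linking facial skin biophysical
    measurements, Baumann-style questionnaire scoring, composite skin-type
    (cutotype) assignment with aging-group stratification, and genus-level
    skin-microbiome community analysis. Provides a synthetic cohort generator
    emulating age-dependent skin trends and planted community structure, a
    questionnaire scoring engine with the published thresholds and bonus
    rules, correlation-based reduction of biophysical parameters to six
    representative metrics, tertile-based HH/HL/LH/LL typing with
    proportion-crossover detection of aging cutpoints, enterotype-style PAM
    clustering with optimal-k consensus and recursive divide-and-compare
    subclustering on generalized UniFrac distances, prevalence plus
    Kruskal-Wallis core-genus selection, group statistics (PERMANOVA,
    LDA effect sizes, pairwise differential abundance), and SMOTE-balanced
    one-vs-rest gradient-boosted type prediction with micro/macro ROC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    cluster,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    picante,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
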