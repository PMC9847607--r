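Package: tbwsj
Title: Temporal Binding Windows from Olfactory-Gustatory Simultaneity Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneity-judgment (SJ) experiments on
    olfactory-gustatory temporal integration. Applies trial-selection rules to
    per-trial SJ records, bins actual stimulus onset asynchronies (SOAs) into
    time windows, fits a Gaussian simultaneity curve by least squares, and
    derives temporal-binding-window (TBW) indices, chiefly the half width at
    half height (HWHH). Includes the accompanying inferential layer (Wilcoxon
    signed-rank tests with effect sizes, Spearman correlation tests), post-hoc
    power via the asymptotic-relative-efficiency noncentral-t method and the
    exact sampling distribution of the correlation coefficient, a-priori
    Wilcoxon-Mann-Whitney sample sizes, and a synthetic-observer generator
    that emulates the SJ experimental design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
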