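Package: hubdrs
Title: Interictal MEG Network Hubs, Resection Overlap, and the D_RS Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sliding-window amplitude-correlation (Pearson) functional
    networks from source-localized MEG region-of-interest time series, computes
    intra-hemispheric node strength, and quantifies how distinguishable
    surgically removed regions are from spared regions with the D_RS statistic
    (a normalized Mann-Whitney U over removed-by-spared node pairs). Includes
    resection labeling from parcellation/mask volumes via the any-voxel-overlap
    rule, group-level outcome discrimination (AUC with logit-transformed
    Hanley-McNeil confidence intervals, one-tailed rank-sum test), robust
    bisquare and mixed-effects duration-connectivity regressions, and a
    synthetic-cohort generator with planted hub, resection, outcome, and
    duration effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    RNifti,
    data.table,
    jsonlite,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
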