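Package: schooldust
Title: Contamination Indices, Health Risk, and Source Apportionment for
    Heavy Metals in School Dust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing site-by-element heavy-metal concentration
    tables from settled dust in schools and similar indoor environments.
    Computes the classical contamination indices (geo-accumulation index,
    contamination factor, modified degree of contamination, pollution load
    index, enrichment factor with an iron crustal reference), a US
    EPA-style non-carcinogenic health-risk assessment for child and adult
    receptors over ingestion, inhalation, and dermal pathways, and
    multivariate source-identification statistics (Pearson correlation,
    principal component analysis, Ward hierarchical clustering, k-means
    with elbow and silhouette diagnostics). Includes an
    uncertainty-weighted positive matrix factorization (PMF) receptor
    model fitted by multiplicative updates with multi-start initialization
    and factor-count selection, plus a synthetic-data generator that
    plants a known low-rank source structure so every stage of the
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
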