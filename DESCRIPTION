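Package: lncdisc
Title: Disease-Related lncRNA Classification from Sequence and Structure Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts disease-associated long non-coding RNA (lncRNA)
    transcripts from sequence- and structure-derived features. Implements
    greedy identity-based redundancy filtering of transcript sets, a
    120-column feature space (2-mer and 3-mer frequencies, parallel-correlation
    pseudo dinucleotide composition, exon-level conservation, GC content,
    protein-interaction and mutation counts, minimum free energy, base-pair
    and unpaired-loop statistics from dot-bracket secondary structures),
    random-forest importance-based feature selection, and classification by
    support vector machine, random forest, and an extreme learning machine,
    evaluated under stratified ten-fold cross-validation with ROC/AUC
    summaries. A Nussinov-style maximum-weight folder and a synthetic data
    generator make the full pipeline runnable and testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
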