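Package: gofunsim
Title: Gene Ontology Functional Similarity with Background Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Protein functional similarity from Gene Ontology (GO)
    annotations. Parses OBO ontologies and GAF 2.x annotation corpora,
    derives term information content, and implements six pairwise
    semantic-similarity measures (Resnik, Lin, Schlicker relevance,
    information coefficient, Jiang-Conrath, graph information content)
    together with five mixing strategies (average, maximum, best-match
    maximum, best-match average, averaged best match) and combined
    multi-ontology scores. Raw scores can be normalized against
    per-protein sampled background distributions to similarity z-scores
    that correct for annotation bias. An orthology-based benchmark
    engine performs optimal-threshold error-rate minimization over
    derangement controls, resampled confidence intervals, and paired
    corpus-comparison tests. A synthetic ontology/corpus/orthology
    generator makes the whole stack testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
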