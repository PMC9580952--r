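Package: ticlust
Title: Taxonomy-Informed Clustering of Denoised 16S rRNA Amplicons
Version: 0.1.0
Authors@R:
    person("TIC", "Maintainers", email = "ticlust@example.org", role = c("aut", "cre"))
Description: Incremental, taxonomy-guided clustering of denoised 16S rRNA
    amplicon sequences (zOTUs) into molecular species (sOTU), genus (gOTU)
    and family (fOTU) units at 97/95/90 percent identity. Sequences are
    clustered only within their classified taxonomic path, so clusters never
    mix known genera or families; unclassified sequences are placed
    incrementally against existing centroids and give rise to novel,
    deterministically named OTUs with placeholder upper ranks. Includes a
    k-nearest-neighbour LCA consensus classifier, cluster-quality metrics
    (purity, adjusted Rand index, normalised mutual information, mixed-clade
    counts), taxonomy-pruning benchmark perturbations, a seeded synthetic
    16S community generator with divergence tiers aligned to the clustering
    cutoffs, alignment coverage/region utilities, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
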