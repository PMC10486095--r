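Package: geneHMM
Title: Gene-Level Chromatin Annotation with Mixtures of Hidden Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns each protein-coding gene, per cell type, to one of a
    small number of gene-level chromatin annotations learned de novo from
    binarized epigenomic mark tracks (histone ChIP-seq, DNase). Each
    annotation is a mixture component that is itself a small hidden Markov
    model with Bernoulli-product emissions, so both the combinatorial and
    the spatial pattern of marks along a gene inform its label. The mixture
    is trained as a single constrained HMM with a dummy state and dummy
    mark separating genes, using scaled Baum-Welch EM with the numerical
    floors needed for long concatenated sequences. Includes TSS,
    gene-average, and collapsed baseline models, a full set of evaluation
    statistics (expression prediction, mutual information with gene length,
    replicate confusion and contingency matrices, co-assignment enrichment,
    gene-set and pLI analyses), and a synthetic-data generator that
    produces ground-truth fixtures with replicate structure and linked
    covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
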