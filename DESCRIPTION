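Package: hmcdiv
Title: Domain-Wise Evolutionary Divergence and Clone-Library SNP
    Analysis for Crustacean Hemocyanin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying domain-wise evolutionary divergence of
    arthropod hemocyanin subunits and the sequence diversity of their
    C-terminal immunoglobulin-like (D3) domain.  Implements pairwise
    maximum-likelihood protein distances under the Jones-Taylor-Thornton
    (JTT) amino-acid substitution model, nonsynonymous/synonymous
    substitution rates (Ka/Ks) by Li's (1993) unweighted-pathway method,
    consensus-unit pattern matching with variable spacer ranges against
    conserved-domain consensi, and clone-library SNP calling with a
    recurrence filter, per-site frequencies and cross-library set
    algebra.  Ships seeded generators for JTT-evolved protein families,
    controlled codon alignments, planted-SNP clone libraries and
    unit-pattern fixtures so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
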