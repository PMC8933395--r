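Package: m7Gseq
Title: TRAC-Seq m7G tRNA Site Calling and Codon-Level Translation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking N7-methylguanosine (m7G) tRNA
    modification to selective mRNA translation. Calls m7G sites on tRNAs
    from TRAC-seq (tRNA reduction and cleavage sequencing) 5'-end pileups
    via a cleavage score gated on the ABGWY variable-loop motif, quantifies
    m7G versus non-m7G tRNA expression changes under methyltransferase
    knockdown, computes FPKM-based translation efficiency from polysome or
    ribosome-footprint libraries, counts m7G-tRNA-decoded codons per mRNA
    under configurable wobble-decoding rules, and measures codon-level
    ribosome pausing. A seeded synthetic-data generator emulates every
    input so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
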