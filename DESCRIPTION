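Package: bcrselect
Title: Simulation and Repertoire Informatics for Antigen-Specific B-Cell
    Bulk Selection and Antibody Library Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying antigen-specific B-cell (AgSC) bulk selection
    and its consequences for antibody discovery. A seeded synthetic-repertoire
    generator simulates an immune response (rare antigen-specific lineages
    with CDR-biased somatic hypermutation), IgM/IgD depletion, magnetic bulk
    selection, and cognate versus combinatorial heavy/kappa chain pairing
    during library construction, with full ground truth. Downstream modules
    assign germline V genes by pairwise alignment, delineate framework and
    CDR regions, emit AIRR-style rearrangement tables, compute clonotype
    uniqueness/sharing and VH/VK family pairing matrices, build
    neighbor-joining trees from Jukes-Cantor distances over concatenated
    six-CDR protein sequences, collapse NGS reads with a minimum-observation
    filter, and provide plate-screening statistics (fold-over-background hit
    calling, robust Z-prime, t and Mann-Whitney tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
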