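Package: magtaq
Title: Split-Site Screening and Light-Induced Genome Rearrangement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for structure-guided engineering of photoactivatable split
    restriction enzymes and for the downstream analysis of the genome
    rearrangements they induce. Provides parsing and superposition of
    predicted protein-DNA complex models with per-atom confidence scores,
    a deterministic Shrake-Rupley solvent-accessible surface area engine,
    buried-interface and hydrogen-bond analysis, Mg2+ coordination geometry,
    inference of cleavage position and overhang from catalytic-ion placement,
    and Pareto-style ranking of candidate split sites against an external
    stability table. A second workflow calls loss-of-heterozygosity tracts
    (short gene conversion versus break-induced replication), aneuploidy and
    translocations (NAHR versus NHEJ-mediated) from hybrid-diploid SNP marker
    tracks and junction records, with recognition-motif breakpoint checks and
    rank-based group comparisons. A synthetic-data module generates toy
    complexes, idealized B-DNA, and ground-truthed hybrid diploid genomes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
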