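Package: palaeokin
Title: Molecular Genealogy from Ancient DNA: Replicate-Consensus STR
    Typing, Lineage-Marker Haplogrouping and Forensic Kinship Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing family relationships among ancient
    skeletal remains from degraded-DNA genotype data. Implements
    replicate-consensus calling for autosomal and Y-chromosomal STR
    profiles with discordance accounting, mitochondrial control-region
    haplotyping in forensic rCRS difference notation with motif-based
    haplogroup assignment, hierarchical Y-haplogroup assignment from
    biallelic markers tolerant of missing data, pairwise kinship
    likelihood ratios under identity-by-descent sharing models with
    Mendelian exclusion, ancient-DNA authenticity checks (researcher
    contamination screening and uracil-DNA-glycosylase clone-versus-direct
    deamination damage detection), and a pedigree simulator with a
    laboratory noise model so every stage can be validated against
    synthetic families with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
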