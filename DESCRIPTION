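Package: slidecyl
Title: Sliding-Cylinder Analysis of Mutual Polymorphism in Protein Contact Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analyses population polymorphism and conservatism on the contact
    surface of a docked protein heterodimer. Builds a gridded midpoint
    surface between two subunits, computes sliding-cylinder diversity maps
    (amino-acid diversity pi and codon-level dN/dS) for each subunit from
    pooled population alignments, combines them into two-channel RG
    classifications of mutually conservative, mutually polymorphic and
    one-sided zones, projects a ligand onto the surface, assembles and
    filters ternary receptor-ligand-receptor poses from binary docking
    poses, and tests the congruence of two population gene trees by
    Gaussian-mixture embedding, Procrustes superimposition with mirror
    reflection, and frequency permutation. Includes a deterministic
    synthetic-data generator producing planted-truth fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
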