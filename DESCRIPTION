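Package: wuchtyfold
Title: Complete Enumeration of Suboptimal RNA Secondary Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combinatorially complete enumeration of non-pseudoknotted RNA
    secondary structures within a free-energy window above the minimum free
    energy, by stack-based refinement of partially determined structures
    bounded with Zuker dynamic-programming tables. Adds energy-independent
    no-lonely-pair pruning, hard and context-dependent chemical-probing
    constraints, optional multibranch loops, a post-hoc helix filter, a
    low-memory depth-first enumeration mode, an exact big-integer structure
    counting dynamic program, landscape metrics (base-pair distance, ensemble
    summaries), and a master-worker parallel driver that reproduces the
    serial result set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, Rcpp, Biostrings, stats
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), parallel, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
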