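#!/usr/bin/env Rscript
# Optional long-running enumeration: the number of weakly connected
# isomorphism classes of loop-free 6-node digraphs (expected: 1,530,843,
# OEIS A003085). Uses growth-based isomorph-free generation from the 9,364
# connected 5-node classes; each of the ~9.6 million candidates is
# canonicalized by exhaustive minimization over 720 relabelings, so expect
# a runtime of hours on one core. Not part of the test suite.

suppressPackageStartupMessages(library(netmotif))

message("growing connected 6-node digraph classes from the 5-node classes ...")
t0 <- proc.time()[3]
classes <- enumerate_connected_classes(6, directed = TRUE, method = "growth")
message(sprintf("connected 6-node digraph classes: %d (expected 1530843)",
                length(classes)))
message(sprintf("elapsed: %.0f s", proc.time()[3] - t0))
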