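#!/usr/bin/env Rscript
# Step 2 — flux density received from one neighbouring cell.
#
# Inverse-square decay of the received chlorophyll fluorescence with
# centre-to-centre distance: ~0.01 umol/m^2/s for touching cells (R = 2r =
# 6 um) falling to 3.6e-5 at 100 um. This is the two-cell scale at which a
# signal would have to act between adjacent cells.

library(fluosignal)
dir.create("results", showWarnings = FALSE)

distances_um <- c(6, 8, 10, 15, 20, 30, 50, 70, 100)
tab <- data.frame(
  distance_um = distances_um,
  cfpfd = pairwise_cfpfd(micrometres(distances_um))
)
write.csv(tab, "results/02_pairwise.csv", row.names = FALSE)

cat("received CFPFD (umol/m^2/s) by centre distance:\n")
print(tab, row.names = FALSE)
cat(sprintf("\nadjacency (6 um): %.4g; 100 um: %.4g — a %.0fx drop\n",
            tab$cfpfd[1], tab$cfpfd[nrow(tab)],
            tab$cfpfd[1] / tab$cfpfd[nrow(tab)]))
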