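#!/usr/bin/env Rscript
# Step 6 — iron-stratified correlation of chlorophyll and ISIP share.
#
# Generates a synthetic station survey whose per-iron-bin correlation between
# chlorophyll content and the normalized ISIP1 expression share mirrors the
# qualitative ocean pattern (strong at intermediate iron, absent at the
# extremes), runs the stratified Pearson analysis, and checks recovery of the
# imposed correlations across 500 seeded surveys.

library(fluosignal)
dir.create("results", showWarnings = FALSE)

tab <- make_station_table(seed = 7, rho = c(0.44, 0.84, 0.66, 0))
write_station_csv(tab, "results/06_stations.csv")
res <- stratified_pearson(tab)
write.csv(res, "results/06_correlations.csv", row.names = FALSE)
cat("per-bin Pearson correlation, chlorophyll vs normalized ISIP1 share:\n")
print(res, row.names = FALSE)

# recovery experiment: three graded correlations, 500 independent surveys
rho <- c(0.85, 0.65, 0.45)
bins <- iron_bins(c(0.9, 0.5, 0.1), c(1.0, 0.6, 0.2))
ranks_ok <- vapply(seq_len(500), function(s) {
  t_s <- make_station_table(seed = s, bins = bins, rho = rho, n_per_bin = 15)
  r <- stratified_pearson(t_s, bins)$r[1:3]
  identical(order(r, decreasing = TRUE), order(rho, decreasing = TRUE))
}, logical(1))
recovery <- data.frame(rho = paste(rho, collapse = "/"),
                       n_per_bin = 15, surveys = 500,
                       rank_order_correct = mean(ranks_ok))
write.csv(recovery, "results/06_recovery.csv", row.names = FALSE)
cat(sprintf("\nrank ordering of per-bin r recovered in %.1f%% of 500 surveys\n",
            100 * mean(ranks_ok)))
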