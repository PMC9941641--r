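#!/usr/bin/env Rscript
# Generate the synthetic proteome-wide MR inputs used throughout the
# analysis: per-protein regional pQTL summary statistics, two case-control
# outcome cohorts (large-case discovery, small-case replication), LD,
# annotation and ground truth. Writes example normalized tables and a
# truth summary under results/.

suppressPackageStartupMessages(library(protmr))

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 20230207, n_snps_per_region = 60)
bundle <- simulate_proteome(cfg, n_proteins = 100, n_causal = 5,
                            n_confounded = 1)

cat("Simulated", nrow(bundle$proteins), "proteins over",
    length(bundle$ld), "regions (",
    sum(bundle$truth$causal), "causal,",
    sum(bundle$truth$status == "confounded"), "LD-confounded ).\n")

# example normalized summary-statistics exports (canonical columns + JSON
# drop-count sidecar)
ex_pid <- bundle$truth$protein_id[bundle$truth$causal][1]
write_sumstats(bundle$exposure[[ex_pid]], "results/example_exposure.tsv")
write_sumstats(bundle$outcome_discovery[
  bundle$outcome_discovery$snp_id %in% bundle$exposure[[ex_pid]]$snp_id, ],
  "results/example_outcome_discovery.tsv")

write.table(bundle$truth, "results/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/example_exposure.tsv, results/example_outcome_discovery.tsv,",
    "results/truth.tsv\n")
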