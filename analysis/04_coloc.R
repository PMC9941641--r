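#!/usr/bin/env Rscript
# Colocalization behaviour across planted architectures: shared causal
# variant (PP.H4 high), distinct causal variants in LD (PP.H3 high - the
# signature of an LD-confounded MR hit), one-trait-only and null regions.
# Writes per-scenario posterior summaries under results/.

suppressPackageStartupMessages(library(protmr))
dir.create("results", showWarnings = FALSE)

run_scenario <- function(scenario, causal_z, n = 50) {
  pps <- t(vapply(seq_len(n), function(i) {
    cfg <- sim_config(seed = 20230207 + i, n_snps_per_region = 200,
                      coloc_scenario = scenario, causal_z = causal_z,
                      distinct_r2 = 0.3)
    r <- simulate_region(cfg)
    coloc_region(r$trait1[, c("beta", "se")], r$trait2[, c("beta", "se")],
                 trait_types = c("quantitative", "case_control"))$pp
  }, numeric(5)))
  colMeans(pps)
}

scen <- rbind(
  shared = run_scenario("shared", c(8, 8)),
  distinct = run_scenario("distinct", c(10, 10)),
  trait1_only = run_scenario("trait1_only", c(10, 0)),
  null = run_scenario("null", c(0, 0))
)
out <- data.frame(scenario = rownames(scen), round(scen, 4),
                  check.names = FALSE)
cat("Mean posterior probabilities over 50 regions per scenario:\n")
print(out, row.names = FALSE)
write.table(out, "results/coloc_scenarios.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/coloc_scenarios.tsv\n")
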