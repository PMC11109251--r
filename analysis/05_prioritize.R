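#!/usr/bin/env Rscript
# Stage 5: relate protection coverage to fishing pressure across 3D realms
# (log-log regression), score realms in the 4 x 4 pressure-coverage grid, and
# classify them into the four conservation priority profiles.

library(realms3d)

coverage <- read.csv("results/tables/coverage.csv", stringsAsFactors = FALSE)
pressure <- read.csv("results/tables/pressure_impacted.csv",
                     stringsAsFactors = FALSE)

summaries <- realm_summaries(coverage, pressure)
write.csv(summaries, "results/tables/summary.csv", row.names = FALSE)

for (field in c("all", "strict")) {
  fit <- loglog_regression(summaries, field)
  cat(sprintf("log10(coverage_%s) ~ log10(pressure): slope %.3f, r %.3f, r2 %.3f, p %.4g (n = %d used, %d dropped)\n",
              field, fit$slope, fit$r, fit$r2, fit$p_value, fit$n_used,
              fit$n_dropped))
}

priority <- prioritize_realms(summaries, assessment = "all")
write.csv(priority, "results/tables/priority.csv", row.names = FALSE)

shares <- profile_shares(priority$profile, priority$area_km2)
cat("\nconservation priority profiles (fraction of realms / of ocean area):\n")
for (i in seq_len(nrow(shares)))
  cat(sprintf("  %-28s %5.1f%% / %5.1f%%\n", shares$profile[i],
              100 * shares$realm_share[i], 100 * shares$area_share[i]))
write.csv(shares, "results/tables/profile_shares.csv", row.names = FALSE)

strict <- prioritize_realms(summaries, assessment = "strict")
write.csv(strict, "results/tables/priority_strict.csv", row.names = FALSE)
cat(sprintf("\nrealms below 5%% strict (Ia/Ib) coverage: %d of %d\n",
            sum(summaries$coverage_strict_pct < 5), nrow(summaries)))
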