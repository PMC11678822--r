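#!/usr/bin/env Rscript
# A priori power and sample size for the pivotal studies, from the exact
# TOST computation: the planning scenarios behind "96 subjects at ISCV
# 50%, GMR 105%" (200 mg) and "106 subjects at ISCV 35%, GMR within
# [90.00-111.11]%" (400 mg), plus a power grid over ISCV.

library(bepilot)

dir.create("results", showWarnings = FALSE)

p96 <- 100 * tost_power(96, 50, 105)
p106 <- 100 * min(tost_power(106, 35, 90), tost_power(106, 35, 111.11))
n50 <- sample_size(50, 105, target_power = 0.80)
n35 <- sample_size(35, c(90, 111.11), target_power = 0.80)
cat(sprintf("200 mg planning: power at n=96, ISCV 50%%, GMR 105%%: %.2f%% (min n for 80%%: %d)\n",
            p96, n50))
cat(sprintf("400 mg planning: worst-case power at n=106, ISCV 35%%, GMR [90-111.11]%%: %.2f%% (min n: %d)\n",
            p106, n35))

grid <- expand.grid(iscv_pct = c(30, 35, 40, 50, 60),
                    gmr_pct = c(95, 100, 105, 110))
grid$n_80 <- mapply(function(cv, g) sample_size(cv, g, 0.80),
                    grid$iscv_pct, grid$gmr_pct)
grid$power_n24_pct <- 100 * mapply(function(cv, g) tost_power(24, cv, g),
                                   grid$iscv_pct, grid$gmr_pct)
write.csv(grid, "results/power_sample_size.csv", row.names = FALSE)
cat("\nSample size for 80% power / exact power of an n=24 pilot:\n")
print(grid, row.names = FALSE)
cat("\nWrote results/power_sample_size.csv\n")
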