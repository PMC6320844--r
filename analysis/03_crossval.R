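#!/usr/bin/env Rscript
# Stage 3: model assessment.
#
# r2 and adjusted r2 describe in-sample fit; Q2_LOO and Q2_LOSO describe
# prediction. With replicates in the data, leave-one-row-out retains a
# solute's siblings in every training fold, so Q2_LOO flatters a model;
# leave-one-solute-out is the honest statistic for predicting genuinely
# new solutes, and it is where the nested model separates from the much
# larger crossed model.

library(mcflfer)

if (!file.exists("results/simulated_observations.csv")) {
  stop("run analysis/01_simulate.R first")
}
obs <- load_observations("results/simulated_observations.csv")

stats <- fit_statistics_table(obs)
print(stats, digits = 3)
utils::write.csv(stats, "results/fit_statistics.csv", row.names = FALSE)

gap <- function(m) stats$q2_loo[stats$model == m] -
  stats$q2_loso[stats$model == m]
cat(sprintf("LOO minus LOSO optimism: single %.3f, crossed %.3f, nested %.3f\n",
            gap("single"), gap("crossed"), gap("nested")))
cat(sprintf("nested minus crossed Q2_LOSO: %.3f\n",
            stats$q2_loso[stats$model == "nested"] -
              stats$q2_loso[stats$model == "crossed"]))
cat("wrote results/fit_statistics.csv\n")
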