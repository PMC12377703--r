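#!/usr/bin/env Rscript
# Step 3 -- confounder-adjusted logistic regression.
#
# Disproportionality is vulnerable to channeling: a drug given mostly to
# the elderly inherits their higher background pulmonary-edema rate.  For
# every consensus drug (and the confounded pioglitazone-like drug, for
# contrast) we regress the event indicator on drug exposure with age,
# sex, weight and report year as covariates, by Newton/IRLS, and flag
# independent risk factors (OR > 1, p < 0.05).

library(dipesignal)

raw <- read_faers("scratch/simulated_faers")
data <- clean_faers(raw, target_pt = "Pulmonary Edema")
signals <- read.delim("results/signal_table.tsv")

drugs <- union(signals$drug[signals$consensus], "PIOGLITAZONE")
adj <- run_adjustment(data, drugs, "Pulmonary Edema", 10037375L)
write.table(adj, "results/adjusted_or.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sum(adj$independent_risk), "of", nrow(adj),
    "drugs remain independent risk factors after adjustment\n")
print(adj[c("drug", "n_used", "or", "or_lo95", "or_hi95", "p_value",
            "independent_risk")], digits = 3)
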