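#!/usr/bin/env Rscript
# Step 2 -- cohort construction and four-method disproportionality.
#
# Parses the quarterly files, keeps 2004Q1-2024Q2 healthcare-professional
# reports, deduplicates case versions, removes reports whose suspect drug
# was indicated for pulmonary edema itself, then screens every drug with
# >= 10 pulmonary-edema cases (as primary suspect) with ROR, PRR, the
# BCPNN information component and EBGM, calling a signal only when all
# four methods agree.

library(dipesignal)

raw <- read_faers("scratch/simulated_faers")
data <- clean_faers(raw, target_pt = "Pulmonary Edema")
print(data)

freq <- rank_frequencies(data, "Pulmonary Edema", min_cases = 10,
                         target_code = 10037375L)
write.table(freq, "results/frequency_ranking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

signals <- signal_table(data, "Pulmonary Edema", min_cases = 10,
                        target_code = 10037375L)
write.table(signals, "results/signal_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)


cat(nrow(freq), "target drugs with >= 10 cases;",
    sum(signals$consensus), "reach four-method consensus\n")
cat("top of the ROR ranking:\n")
print(head(signals[c("drug", "a", "ror", "ror_lo95", "prr", "ic025",
                     "ebgm", "eb05", "consensus")], 8), digits = 3)
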