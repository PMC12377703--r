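#!/usr/bin/env Rscript
# Step 4 -- time to onset, stratified by age (>= 65) and sex.
#
# For each drug of interest, onset = event date minus the earliest
# day-precision therapy start of that drug as primary suspect; partial
# dates and negative intervals are dropped with reason codes.  Strata are
# compared with a two-sided Mann-Whitney test (exact at small n).

library(dipesignal)

raw <- read_faers("scratch/simulated_faers")
data <- clean_faers(raw, target_pt = "Pulmonary Edema")
signals <- read.delim("results/signal_table.tsv")
drugs <- union(signals$drug[signals$consensus],
               c("DILTIAZEM", "TADALAFIL"))  # built-in stratum shifts

records <- do.call(rbind, lapply(drugs, function(d) {
  compute_onset(data, d, "Pulmonary Edema", 10037375L)$records
}))

summaries <- do.call(rbind, lapply(split(records, records$drug),
  function(s) cbind(drug = s$drug[1], summarize_onset(s$onset_days))))
strat <- rbind(stratified_onset_analysis(records, "age"),
               stratified_onset_analysis(records, "sex"))
write.table(summaries, "results/onset_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(strat, "results/onset_stratified.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

short <- summaries$drug[summaries$median < 30]
cat("median onset under 30 days:", paste(short, collapse = ", "), "\n")
sig <- strat[strat$significant %in% TRUE, ]
cat("significant stratum differences:\n")
print(sig[c("drug", "stratum_variable", "n1", "n2", "mean1", "mean2",
            "p_value", "direction")], digits = 3)
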