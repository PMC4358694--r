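#!/usr/bin/env Rscript
# Generate the two synthetic datasets the downstream analyses consume:
# an alligator-like cranial measurement series (108 specimens, 22 variables
# with published intercepts/slopes/R-squared, log-uniform sizes 29-689 mm,
# 1-mm rounding) and a literature-survey table (542 samples across the four
# vertebrate/invertebrate x extant/extinct cells).
suppressPackageStartupMessages(library(allopower))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

tab <- simulate_dataset(alligator_like_spec(), 108, seed = seed)
write_measurement_table(tab, "results/synthetic_measurements.csv")
cat(sprintf("measurement series: %d specimens x %d variables, reference %s, sizes %.0f-%.0f mm\n",
            nrow(tab$values), ncol(tab$values), tab$reference_id,
            min(reference_values(tab)), max(reference_values(tab))))

sv <- simulate_survey(default_survey_spec(), seed = seed + 2)
utils::write.csv(sv, "results/synthetic_survey.csv", row.names = FALSE)
cat(sprintf("survey: %d samples, n range %d-%d\n", nrow(sv), min(sv$n),
            max(sv$n)))
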