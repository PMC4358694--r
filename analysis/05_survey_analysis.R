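#!/usr/bin/env Rscript
# Literature-survey sample-size analysis: summarize the four
# vertebrate/invertebrate x extant/extinct cells (N, min, max, mean, median,
# share of samples at n <= 10) and compare the cells with two-sample
# Kolmogorov-Smirnov tests. Extinct cells are expected to sit well left of
# extant ones -- the sample-size regime where false isometry dominates.
suppressPackageStartupMessages(library(allopower))

sv <- read_survey_table("results/synthetic_survey.csv")
rep <- report_survey(sv, "results/survey_summary.csv",
                     "results/survey_comparisons.csv")
print(rep$summary, row.names = FALSE)
print(rep$comparisons, row.names = FALSE)
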