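#!/usr/bin/env Rscript
# Stage 4: adjudicate outcomes across the three record sources. The
# free-text search runs in practices with an above-median volume of text
# per patient, from 2006 onwards, over notes within three weeks of death;
# case ascertainment then applies the source-precedence hierarchy (death
# certificate, free text, primary-care code) and the three nested
# sudden-cardiac-death definitions with their hospitalisation exclusions.

library(apcohort)
library(data.table)
setDTthreads(1L)

ehr <- read_ehr("results/ehr")
subjects <- fread("results/cohorts.csv")

ft <- search_free_text(ehr$freetext, ehr$patients,
                       start_year = 2006, origin_date = ehr$origin_date)
fwrite(ft, "results/free_text_matches.csv")

adj <- adjudicate_outcomes(subjects, ehr$events, ft, ehr$patients)
fwrite(adj, "results/outcomes.csv")

cat("free-text matches:", nrow(ft),
    "(", sum(ft$verdict == "scd"), "counted as sudden cardiac death )\n")
cat("adjudicated events by outcome:\n")
print(adj[, .N, by = outcome])
cat("winning sources for the narrow sudden-cardiac-death definition:\n")
print(adj[outcome == "scd_primary", .N, by = winning_source])
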