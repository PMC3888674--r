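#!/usr/bin/env Rscript
# Stage 2: construct the three analysis cohorts from the generated tables —
# antipsychotic users (indexed at first observed prescription, split into
# incident and prevalent), 1:3 matched general-population controls (same
# practice and sex, birth year within two years, index date inherited and
# at least twelve months after the control's collection start), and the
# unmatched psychiatric-nonuser cohort (indexed at first diagnosis,
# censored at any later antipsychotic prescription) — then apply the
# cardiac exclusion rules.

library(apcohort)
library(data.table)
setDTthreads(1L)

ehr <- read_ehr("results/ehr")

users <- identify_users(ehr$patients, ehr$prescriptions)
controls <- match_controls(users, ehr$patients, ehr$prescriptions,
                           match_criteria(), seed = 20260925L)
nonusers <- identify_psych_nonusers(ehr$patients, ehr$prescriptions)
subjects <- apply_exclusions(rbind(users, controls, nonusers),
                             ehr$events, ehr$patients)

fwrite(subjects, "results/cohorts.csv")
fwrite(attr(subjects, "exclusion_flow"), "results/exclusion_flow.csv")
fwrite(attr(controls, "match_summary"), "results/match_summary.csv")

cat("cohort sizes after exclusions:\n")
print(subjects[, .N, by = cohort])
cat("incident / prevalent users:\n")
print(subjects[cohort == "user", .N, by = user_type])
cat("controls per user: mean",
    round(mean(attr(controls, "match_summary")$n_controls), 2), "\n")
print(attr(subjects, "exclusion_flow"))
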