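#!/usr/bin/env Rscript
# Stage 1: generate the synthetic linked-record study population.
#
# Emulates a primary-care database linked to hospital episodes and death
# certificates: 50,000 patients over a ten-year collection window, with
# psychiatric diagnoses, antipsychotic prescribing (typical and atypical,
# with dose targets spanning the chlorpromazine-equivalent bands), deaths
# from competing causes, nonfatal cardiac events, hospital episodes and
# free-text notes around deaths. All downstream stages read the four
# delimited tables this stage writes.

library(apcohort)
library(data.table)
setDTthreads(1L)

# Planted truth: current antipsychotic exposure multiplies every death
# cause by 1.75, so each mortality outcome has a true current-use rate
# ratio of 1.75 against psychiatric nonusers; the nonfatal outcomes are
# null. Stage 5's estimates can be read directly against these values.
cfg <- sim_config(n_patients = 50000, seed = 20260925,
                  true_rr = list(all_cause_mortality = 1.75))
sim <- simulate_ehr(cfg)
dir.create("results", showWarnings = FALSE)
write_ehr(sim, "results/ehr")

v <- validate_inputs(sim)
fwrite(v, "results/input_validation.csv")

cat("patients:       ", nrow(sim$patients), "\n")
cat("prescriptions:  ", nrow(sim$prescriptions), "\n")
cat("coded events:   ", nrow(sim$events), "\n")
cat("free-text notes:", nrow(sim$freetext), "\n")
cat("deaths:         ", sim$patients[!is.na(death_date), .N], "\n")
cat("tables written to results/ehr/\n")
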