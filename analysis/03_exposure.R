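#!/usr/bin/env Rscript
# Stage 3: standardise prescriptions and build the time-varying exposure
# timelines. Daily doses are converted to chlorpromazine equivalents
# (validity range 25-1000 mg/day) and durations estimated as quantity over
# daily dose (validity 1-91.4 days), both with two-level median imputation;
# prescriptions are stitched into current/recent/past exposure with the
# 30.4-day grace period, and current time is sub-segmented by dose band and
# cumulative-duration band.

library(apcohort)
library(data.table)
setDTthreads(1L)

ehr <- read_ehr("results/ehr")
subjects <- fread("results/cohorts.csv")

episodes <- prepare_episodes(ehr$prescriptions)
fwrite(imputation_summary(episodes), "results/imputation_summary.csv")

timelines <- build_timelines(
  episodes, subjects[cohort == "user", .(patient_id, censor_date)])
fwrite(timelines, "results/exposure.csv")

cat("prescriptions standardised:", nrow(episodes), "\n")
print(imputation_summary(episodes))
cur <- timelines[state == "current"]
cat("exposure intervals:", nrow(timelines),
    "| current person-years:",
    round(sum(cur$end - cur$start) / 365.25), "\n")
cat("current time by dose band (person-years):\n")
print(cur[, .(py = round(sum(end - start) / 365.25, 1)), by = dose_band])
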