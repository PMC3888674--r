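# Outcome and exclusion code sets.
#
# ICD-10 entries are matched hierarchically: an entry matches any recorded
# code of which it is a prefix after dots are removed (I47 matches I47.2).
# Primary-care entries are compact internal stand-in codes ("Read-like"),
# mapped 1:1 from the ICD-10 entries as "RC_" + dotless code; no attempt is
# made to model real Read or Multilex dictionaries.
icd10:
  cardiac_mortality: [I10, I11.9, I20, I21, I22, I23, I24, I25, I42.8, I42.9,
                      I46, I47, I49.0, I49.8, I49.9, I51.6, I51.9, I70.9,
                      R09.2, R96, R98]
  scd_primary: [I46, I47.2, I49.0, R09.2, R96]
  # Broader set nesting the primary one (Ray-style definition). R96 is kept
  # as the whole block so every primary-set code is also a secondary-set code.
  scd_secondary: [I10, I11.9, I20, I21, I22, I23, I24, I25, I42.8, I42.9,
                  I46, I47, I49.0, I49.8, I49.9, I51.6, I51.9, I70.9,
                  R09.2, R96, R98]
  chd: [I21, I22]
  ventricular_arrhythmia: [I49.0]
  # intentional self-harm block, X60-X84
  suicide: [X60, X61, X62, X63, X64, X65, X66, X67, X68, X69,
            X70, X71, X72, X73, X74, X75, X76, X77, X78, X79,
            X80, X81, X82, X83, X84]
primary_care:
  chd: [CHD01, CHD02]
  ventricular_arrhythmia: [VA001]
  psych:
    schizophrenia: PSY_SCZ
    bipolar: PSY_BIP
    major_depression: PSY_DEP
    dementia: PSY_DEM
exclusion_conditions:
  # disqualify at any time in the record
  any_time: [CCD01, CMYO1, CMYO2]
  # disqualify on/before registration and again on/before the index date:
  # life-threatening ventricular tachyarrhythmia, cardioversion, aborted
  # cardiac arrest, defibrillator implantation
  pre_index: [VTAC1, CVRT1, ACAR1, ICDI1]
free_text:
  # each trigger is a set of case-insensitive substrings that must all occur
  triggers:
    - [dropped dead]
    - [died unexpectedly]
    - [sudden cardiac death]
    - [death, cause unknown]
    - [acute cardiac death]
    - [unexpected, death]
    - [mors subita]
    - [death instanta]
    - [died instanta]
    - [sudden death]
    - [died suddenly]
  # a matched note is counted as a sudden-cardiac-death case unless the text
  # clearly specifies another cause of death (editable list)
  exclusions:
    - motor vehicle accident
    - road traffic accident
    - overdose
    - suicide
    - terminal care
    - metastatic
    - drowning
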