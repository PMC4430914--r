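region,variant,diabetes,gender,smoker,age_band,sbp_band,tc_band,category
synthetic,LI,FALSE,female,FALSE,40-49,lt140,NA,R0_10
synthetic,LI,FALSE,female,FALSE,40-49,140-159,NA,R0_10
synthetic,LI,FALSE,female,FALSE,40-49,160-179,NA,R10_20
synthetic,LI,FALSE,female,FALSE,40-49,180+,NA,R30_40
synthetic,LI,FALSE,female,FALSE,50-59,lt140,NA,R0_10
synthetic,LI,FALSE,female,FALSE,50-59,140-159,NA,R0_10
synthetic,LI,FALSE,female,FALSE,50-59,160-179,NA,R20_30
synthetic,LI,FALSE,female,FALSE,50-59,180+,NA,R40_PLUS
synthetic,LI,FALSE,female,FALSE,60-69,lt140,NA,R0_10
synthetic,LI,FALSE,female,FALSE,60-69,140-159,NA,R10_20
synthetic,LI,FALSE,female,FALSE,60-69,160-179,NA,R30_40
synthetic,LI,FALSE,female,FALSE,60-69,180+,NA,R40_PLUS
synthetic,LI,FALSE,female,FALSE,70+,lt140,NA,R0_10
synthetic,LI,FALSE,female,FALSE,70+,140-159,NA,R20_30
synthetic,LI,FALSE,female,FALSE,70+,160-179,NA,R40_PLUS
synthetic,LI,FALSE,female,FALSE,70+,180+,NA,R40_PLUS
synthetic,LI,FALSE,female,TRUE,40-49,lt140,NA,R0_10
synthetic,LI,FALSE,female,TRUE,40-49,140-159,NA,R0_10
synthetic,LI,FALSE,female,TRUE,40-49,160-179,NA,R20_30
synthetic,LI,FALSE,female,TRUE,40-49,180+,NA,R40_PLUS
synthetic,LI,FALSE,female,TRUE,50-59,lt140,NA,R0_10
synthetic,LI,FALSE,female,TRUE,50-59,140-159,NA,R10_20
synthetic,LI,FALSE,female,TRUE,50-59,160-179,NA,R30_40
synthetic,LI,FALSE,female,TRUE,50-59,180+,NA,R40_PLUS
synthetic,LI,FALSE,female,TRUE,60-69,lt140,NA,R0_10
synthetic,LI,FALSE,female,TRUE,60-69,140-159,NA,R20_30
synthetic,LI,FALSE,female,TRUE,60-69,160-179,NA,R40_PLUS
synthetic,LI,FALSE,female,TRUE,60-69,180+,NA,R40_PLUS
synthetic,LI,FALSE,female,TRUE,70+,lt140,NA,R10_20
synthetic,LI,FALSE,female,TRUE,70+,140-159,NA,R30_40
synthetic,LI,FALSE,female,TRUE,70+,160-179,NA,R40_PLUS
synthetic,LI,FALSE,female,TRUE,70+,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,FALSE,40-49,lt140,NA,R0_10
synthetic,LI,FALSE,male,FALSE,40-49,140-159,NA,R0_10
synthetic,LI,FALSE,male,FALSE,40-49,160-179,NA,R20_30
synthetic,LI,FALSE,male,FALSE,40-49,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,FALSE,50-59,lt140,NA,R0_10
synthetic,LI,FALSE,male,FALSE,50-59,140-159,NA,R10_20
synthetic,LI,FALSE,male,FALSE,50-59,160-179,NA,R30_40
synthetic,LI,FALSE,male,FALSE,50-59,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,FALSE,60-69,lt140,NA,R0_10
synthetic,LI,FALSE,male,FALSE,60-69,140-159,NA,R20_30
synthetic,LI,FALSE,male,FALSE,60-69,160-179,NA,R40_PLUS
synthetic,LI,FALSE,male,FALSE,60-69,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,FALSE,70+,lt140,NA,R10_20
synthetic,LI,FALSE,male,FALSE,70+,140-159,NA,R30_40
synthetic,LI,FALSE,male,FALSE,70+,160-179,NA,R40_PLUS
synthetic,LI,FALSE,male,FALSE,70+,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,40-49,lt140,NA,R0_10
synthetic,LI,FALSE,male,TRUE,40-49,140-159,NA,R10_20
synthetic,LI,FALSE,male,TRUE,40-49,160-179,NA,R30_40
synthetic,LI,FALSE,male,TRUE,40-49,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,50-59,lt140,NA,R0_10
synthetic,LI,FALSE,male,TRUE,50-59,140-159,NA,R20_30
synthetic,LI,FALSE,male,TRUE,50-59,160-179,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,50-59,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,60-69,lt140,NA,R10_20
synthetic,LI,FALSE,male,TRUE,60-69,140-159,NA,R30_40
synthetic,LI,FALSE,male,TRUE,60-69,160-179,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,60-69,180+,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,70+,lt140,NA,R20_30
synthetic,LI,FALSE,male,TRUE,70+,140-159,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,70+,160-179,NA,R40_PLUS
synthetic,LI,FALSE,male,TRUE,70+,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,40-49,lt140,NA,R0_10
synthetic,LI,TRUE,female,FALSE,40-49,140-159,NA,R10_20
synthetic,LI,TRUE,female,FALSE,40-49,160-179,NA,R30_40
synthetic,LI,TRUE,female,FALSE,40-49,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,50-59,lt140,NA,R0_10
synthetic,LI,TRUE,female,FALSE,50-59,140-159,NA,R20_30
synthetic,LI,TRUE,female,FALSE,50-59,160-179,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,50-59,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,60-69,lt140,NA,R10_20
synthetic,LI,TRUE,female,FALSE,60-69,140-159,NA,R30_40
synthetic,LI,TRUE,female,FALSE,60-69,160-179,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,60-69,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,70+,lt140,NA,R20_30
synthetic,LI,TRUE,female,FALSE,70+,140-159,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,70+,160-179,NA,R40_PLUS
synthetic,LI,TRUE,female,FALSE,70+,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,40-49,lt140,NA,R0_10
synthetic,LI,TRUE,female,TRUE,40-49,140-159,NA,R20_30
synthetic,LI,TRUE,female,TRUE,40-49,160-179,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,40-49,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,50-59,lt140,NA,R10_20
synthetic,LI,TRUE,female,TRUE,50-59,140-159,NA,R30_40
synthetic,LI,TRUE,female,TRUE,50-59,160-179,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,50-59,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,60-69,lt140,NA,R20_30
synthetic,LI,TRUE,female,TRUE,60-69,140-159,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,60-69,160-179,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,60-69,180+,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,70+,lt140,NA,R30_40
synthetic,LI,TRUE,female,TRUE,70+,140-159,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,70+,160-179,NA,R40_PLUS
synthetic,LI,TRUE,female,TRUE,70+,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,40-49,lt140,NA,R0_10
synthetic,LI,TRUE,male,FALSE,40-49,140-159,NA,R20_30
synthetic,LI,TRUE,male,FALSE,40-49,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,40-49,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,50-59,lt140,NA,R10_20
synthetic,LI,TRUE,male,FALSE,50-59,140-159,NA,R30_40
synthetic,LI,TRUE,male,FALSE,50-59,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,50-59,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,60-69,lt140,NA,R20_30
synthetic,LI,TRUE,male,FALSE,60-69,140-159,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,60-69,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,60-69,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,70+,lt140,NA,R30_40
synthetic,LI,TRUE,male,FALSE,70+,140-159,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,70+,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,FALSE,70+,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,40-49,lt140,NA,R10_20
synthetic,LI,TRUE,male,TRUE,40-49,140-159,NA,R30_40
synthetic,LI,TRUE,male,TRUE,40-49,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,40-49,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,50-59,lt140,NA,R20_30
synthetic,LI,TRUE,male,TRUE,50-59,140-159,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,50-59,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,50-59,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,60-69,lt140,NA,R30_40
synthetic,LI,TRUE,male,TRUE,60-69,140-159,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,60-69,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,60-69,180+,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,70+,lt140,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,70+,140-159,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,70+,160-179,NA,R40_PLUS
synthetic,LI,TRUE,male,TRUE,70+,180+,NA,R40_PLUS
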