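region,timepoint,storage_kpa,loss_kpa
cerebrum,in_vivo,1.13,0.30
cerebrum,pm_3min,1.42,0.48
cerebrum,pm_45min,1.58,0.61
cerebrum,ex_vivo_16h,1.52,2.36
cerebrum,in_situ_16h,2.60,1.02
cerebellum,in_vivo,0.88,0.33
cerebellum,pm_3min,1.03,0.48
cerebellum,pm_45min,1.29,0.56
cerebellum,ex_vivo_16h,NA,NA
cerebellum,in_situ_16h,2.36,0.95
corpus_callosum,in_vivo,1.22,0.43
corpus_callosum,pm_3min,1.93,0.76
corpus_callosum,pm_45min,2.95,1.14
corpus_callosum,ex_vivo_16h,NA,NA
corpus_callosum,in_situ_16h,4.57,2.26
thalamus,in_vivo,1.14,0.32
thalamus,pm_3min,1.57,0.59
thalamus,pm_45min,1.84,1.30
thalamus,ex_vivo_16h,NA,NA
thalamus,in_situ_16h,2.59,1.69
brainstem,in_vivo,1.01,0.20
brainstem,pm_3min,1.09,0.19
brainstem,pm_45min,1.08,0.30
brainstem,ex_vivo_16h,NA,NA
brainstem,in_situ_16h,1.49,0.39
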