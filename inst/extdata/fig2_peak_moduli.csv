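region,peak_storage_kpa,peak_loss_kpa
cerebrum,1.13,0.30
cerebellum,1.00,0.32
corpus_callosum,1.22,0.57
thalamus,1.14,0.48
brainstem,1.19,0.19
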