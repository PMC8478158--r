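# Demo pipeline configuration: a small simulated healthy cohort.
n_donors: 2
events_per_timepoint: 5000
condition: IR_2Gy
seed: 1
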