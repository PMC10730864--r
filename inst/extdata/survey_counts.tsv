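label	k	n
BAP probe only at initial work-up	23	54
BAP plus IGH/MYC D-FISH at initial work-up	30	54
BAP plus IGH, IGK and IGL D-FISH at initial work-up	1	54
BCL2/BCL6 rearrangements sought upfront	36	54
BCL2/BCL6 sought only after a MYC rearrangement	14	54
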