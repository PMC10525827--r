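trial_id,behavior,frame
example,BeakOpening,19630
example,BeakOpening,20110
example,Mandibulation,5200
example,BeakShift,6200
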