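sample_id	phase
s1	D0
s2	D0
s3	D30
s4	D30
s5	Y1
s6	Y1
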