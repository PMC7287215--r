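feature_id	s1	s2	s3	s4	s5	s6
p01	7.91	8.10	8.35	8.21	8.05	7.98
p02	8.13	8.02	8.41	8.30	8.12	8.04
p03	9.20	9.11	7.95	8.02	8.00	7.89
p04	9.02	9.25	8.10	7.93	8.08	7.95
p05	7.80	7.95	8.01	8.11	9.10	9.22
p06	8.25	8.19	8.06	8.14	7.92	8.03
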