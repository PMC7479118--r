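# Published equilibrium stability measurements for tandem-domain constructs.
# p: single-domain unfolded probability (bootstrap s.t.d.);
# dphi: conformational free-energy difference in kBT (error propagated from
# the 10% force-calibration uncertainty); *_ref: published derived values.
domain	force_pN	force_se	temperature_C	p	p_se	dphi_kBT	dphi_se	dG_ref	dG_ref_se	dG0_ref	dG0_ref_se	Fc_ref	Fc_ref_se
SR4	5.7	0.57	23	0.091	0.002	10.90	2.03	-2.30	0.02	-13.2	2.0	6.3	0.5
SR4	5.7	0.57	27	0.283	0.004	10.38	2.01	-0.93	0.02	-11.3	2.0	6.0	0.6
SR4	5.7	0.57	29	0.531	0.005	10.31	1.99	0.12	0.02	-10.2	2.0	5.7	0.6
SR4	5.7	0.57	31	0.722	0.008	10.15	1.96	0.95	0.04	-9.2	2.0	5.4	0.6
I27	4.5	0.45	23	0.131	0.004	6.44	1.1	-1.89	0.05	-8.3	1.0	5.4	0.4
I27	3.5	0.35	37	0.272	0.004	3.95	0.7	-0.98	0.04	-4.9	0.7	3.9	0.3
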