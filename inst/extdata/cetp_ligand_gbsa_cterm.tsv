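id	E_ele	sd_ele	E_vdw	sd_vdw	G_sur	sd_sur	G_GB	sd_GB	G_bind	sd_bind
ZINC000002010603	-5.8	3.1	-17.5	1.1	-10.1	0.7	0.4	2.7	-32.9	2.3
ZINC000006248133	-9.1	2.3	-19.6	0.8	-13.0	0.6	3.2	2.0	-38.8	1.6
ZINC000005871812	-2.8	1.6	-26.6	0.8	-15.5	0.4	-0.4	1.3	-45.3	1.3
ZINC000002261174	-2.7	1.3	-19.0	0.9	-11.5	0.6	-0.3	1.1	-33.5	1.8
ZINC000003526223	-7.0	1.7	-28.5	0.8	-16.5	0.5	5.5	1.6	-46.5	1.3
ZINC000005871644	-5.1	1.6	-23.1	0.8	-14.3	0.5	3.1	1.4	-39.4	1.4
ZINC000007067674	-2.3	1.2	-26.1	0.6	-15.6	0.3	0.6	1.1	-43.4	1.0
ZINC000006242926	-1.4	1.2	-25.9	0.9	-15.0	0.5	0.1	1.1	-42.2	1.4
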