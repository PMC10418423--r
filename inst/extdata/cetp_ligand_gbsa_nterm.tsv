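id	E_ele	sd_ele	E_vdw	sd_vdw	G_sur	sd_sur	G_GB	sd_GB	G_bind	sd_bind
ZINC000002010603	-2.2	1.5	-14.2	0.9	-8.9	0.5	1.7	0.1	-23.6	0.2
ZINC000006248133	-5.5	2.0	-12.6	1.0	-8.4	0.7	1.1	1.5	-25.4	2.1
ZINC000005871812	-5.6	1.8	-13.1	1.1	-8.7	0.7	2.0	1.3	-25.4	2.1
ZINC000002261174	-5.8	1.4	-19.5	0.9	-12.3	0.6	2.5	1.0	-35.0	1.7
ZINC000003526223	0.0	0.5	-0.1	0.9	-0.1	0.7	-0.1	0.4	-0.2	0.2
ZINC000005871644	-2.6	1.4	-14.9	1.2	-9.7	0.8	0.9	1.1	-26.3	2.3
ZINC000007067674	-2.2	1.4	-11.3	1.5	-7.0	0.1	0.7	1.1	-19.7	2.8
ZINC000006242926	-2.5	1.1	-19.5	0.8	-11.2	0.5	0.6	0.9	-32.6	1.5
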