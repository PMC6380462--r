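ec	cofactor
EC1.1.1.1	NAD(P)H
EC1.1.1.10	NAD(P)H
EC1.1.1.14	NAD(P)H
EC1.1.1.21	NAD(P)H
EC1.1.1.22	NAD(P)H
EC1.1.1.30	NAD(P)H
EC1.1.1.42	NAD(P)H
EC1.1.1.44	NAD(P)H
EC1.1.1.45	NAD(P)H
EC1.1.1.49	NAD(P)H
EC1.1.1.62	NAD(P)H
EC1.1.1.63	NAD(P)H
EC1.1.1.64	NAD(P)H
EC1.1.1.105	NAD(P)H
EC1.1.1.146	NAD(P)H
EC1.1.1.149	NAD(P)H
EC1.1.1.205	NAD(P)H
EC1.1.1.270	NAD(P)H
EC1.1.1.284	NAD(P)H
EC1.2.1.3	NAD(P)H
EC1.2.1.5	NAD(P)H
EC1.2.1.8	NAD(P)H
EC1.2.1.31	NAD(P)H
EC1.2.1.36	NAD(P)H
EC1.2.1.47	NAD(P)H
EC1.3.1.2	NAD(P)H
EC1.3.1.3	NAD(P)H
EC1.3.1.24	NAD(P)H
EC1.5.1.30	NAD(P)H
EC1.8.1.7	NAD(P)H
EC1.8.1.9	NAD(P)H
EC1.11.1.6	NAD(P)H
EC1.11.1.9	NAD(P)H
EC1.11.1.12	NAD(P)H
EC1.14.13.8	NAD(P)H
EC1.14.13.17	NAD(P)H
EC1.14.13.100	NAD(P)H
EC1.15.1.1	NAD(P)H
EC1.17.1.4	NAD(P)H
EC1.10.2.2	cytochrome
EC1.1.3.8	oxygen
EC1.2.3.1	oxygen
EC1.3.3.3	oxygen
EC1.3.3.4	oxygen
EC1.4.3.4	oxygen
EC1.16.3.1	oxygen
EC1.17.3.2	oxygen
EC1.8.4.2	disulfide
EC1.17.4.1	disulfide
EC1.14.14.1	flavin
EC1.14.15.3	iron-sulfur
EC1.14.15.4	iron-sulfur
EC1.14.15.5	iron-sulfur
EC1.14.15.6	iron-sulfur
EC2.1.1.6	S-adenosyl methionine
EC2.1.1.67	S-adenosyl methionine
EC2.3.1.5	acyl-CoA
EC2.3.1.15	acyl-CoA
EC2.3.1.20	acyl-CoA
EC2.3.1.37	acyl-CoA
EC2.3.1.75	acyl-CoA
EC2.3.1.76	acyl-CoA
EC2.3.1.135	acyl-CoA
EC2.3.2.2	acyl-CoA
EC2.3.2.4	acyl-CoA
EC2.4.1.17	nucleotide sugar
EC2.4.1.22	nucleotide sugar
EC2.4.1.38	nucleotide sugar
EC2.4.1.50	nucleotide sugar
EC2.4.1.66	nucleotide sugar
EC2.4.1.90	nucleotide sugar
EC2.4.1.109	nucleotide sugar
EC2.4.1.152	nucleotide sugar
EC2.4.1.221	nucleotide sugar
EC2.4.1.222	nucleotide sugar
EC2.4.2.3	nucleotide sugar
EC2.4.2.8	nucleotide sugar
EC2.4.2.10	nucleotide sugar
EC2.4.99.1	nucleotide sugar
EC2.4.99.6	nucleotide sugar
EC2.5.1.18	glutathione
EC2.5.1.61	glutathione
EC2.7.1.17	ATP
EC2.7.1.21	ATP
EC2.7.1.48	ATP
EC2.7.4.9	ATP
EC2.7.7.9	ATP
EC2.7.11.22	ATP
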