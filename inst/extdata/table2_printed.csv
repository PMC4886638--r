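analyte,fl_chisq,fl_p,conc_chisq,conc_p
April (42),29.9083,3.17e-05,16.7169,0.007832
Baff (37),113.643,2.2e-16,62.002,4.39e-12
CD163 (46),238.8243,2.2e-16,203.1032,2.2e-16
CD30 (53),211.2805,2.2e-16,85.6809,2.2e-16
Chitinase (72),424.5781,2.2e-16,317.3054,2.2e-16
gp130 (14),103.0032,2.2e-16,131.1003,2.2e-16
IFN-a2 (20),6.3883,0.84757,16.7829,0.007832
IFN-b (44),7.8082,0.5516,11.4468,0.047698
IFN-g (21),8.8317,0.41099,33.9826,3.4e-06
IL-10 (56),3.907,1,4.4864,0.640518
IL-11 (39),0.8161,1,,
IL-12p40 (28),3.2292,1,12.739,0.031419
IL-12p70 (75),1.0107,1,1.356,1
IL-19 (29),358.3435,2.2e-16,167.5504,2.2e-16
IL-2 (38),2.5195,1,35.0154,2.18e-06
IL-20 (30),8.292,0.48416,17.9174,0.005032
IL-22 (18),14.932,0.03001,29.4719,2.85e-05
IL-26 (22),12.2377,0.09918,13.608,0.024432
IL-27 (13),16.4034,0.01781,20.5327,0.00158
IL-28 (66),1.7238,1,10.1141,0.070482
IL-29 (33),5.8678,0.9458,26.1033,0.000127
IL-32 (35),76.6646,3.66e-15,73.4943,1.6e-14
IL-34 (15),11.9239,0.10708,,
IL-35 (34),15.7757,0.02143,15.6706,0.010597
IL-6RA (19),233.956,2.2e-16,208.3386,2.2e-16
IL-8 (54),544.3097,2.2e-16,223.1665,2.2e-16
Light (51),29.2716,4.12e-05,,
MMP-1 (43),7.5231,0.56967,56.0105,7.94e-11
MMP-2 (26),244.5459,2.2e-16,180.0698,2.2e-16
MMP-3 (45),228.2042,2.2e-16,,
OCN (65),255.3559,2.2e-16,233.1102,2.2e-16
OPN (77),717.7917,2.2e-16,225.871,2.2e-16
Pentraxin (48),131.4268,2.2e-16,136.3573,2.2e-16
TNFR1 (73),28.7805,4.98e-05,29.273,2.94e-05
TNFR2 (67),274.9578,2.2e-16,193.6078,2.2e-16
TSLP (52),1.3719,1,0.5499,1
Tweak (62),16.2958,0.01781,21.084,0.001315
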