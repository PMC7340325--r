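bin_center	weight
3	0.000221463783863675
5	0.00329135425477531
7	0.0140293961471969
9	0.0324922833073108
11	0.0523564899295078
13	0.0663102494198641
15	0.0707413050153909
17	0.0663684821600312
19	0.0563496966415697
21	0.0441731469653761
23	0.0324398595185056
25	0.0225624795913875
27	0.0149872004543392
29	0.00957056170051505
31	0.00590639553695361
33	0.00353778740027404
35	0.00206392077424354
37	0.00117619528632813
39	0.000656391264200197
41	0.000359462840513076
43	0.000193523510178836
45	0.00010258317141815
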