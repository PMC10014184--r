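reaction	pathway	gpr
MAR00255	fatty acid activation in cytosol	Acsbg1 or Acsbg2 or Acsl1 or Acsl3 or Acsl4 or Acls5 or Acsl6 or Meikin or Slc27a2
MAR02657	carnitine shuttle in cytosol	Cpt1a or Cpt1b or Cpt1c
MAR00110	fatty acid oxidation	Slc25a20
MAR02592	carnitine shuttle in mitochondria	Slc25a20 or Slc25a29
MAR03226	beta-oxidation of unsaturated fatty acids (n-9) in mitochondria	Acad9 or Acadl or Acadm or Acadvl
MAR03227	beta-oxidation of unsaturated fatty acids (n-9) in mitochondria	Echs1 and Ehhadh and Hadha
MAR03228	beta-oxidation of unsaturated fatty acids (n-9) in mitochondria	Hadh and Hadha and Hsd17b10
MAR03229	beta-oxidation of unsaturated fatty acids (n-9) in mitochondria	Acaa2 and Hadha and Hadhb
MAR02635	carnitine shuttle in mitochondria	Cpt2 or Crat
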