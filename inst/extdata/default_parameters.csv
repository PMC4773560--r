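"name","value","unit","group"
"k_CholesterolTransport",0.001,"1/h","transport"
"k_CEH",0.05,"1/h","transport"
"k_f_MTR",0.3,"1/h","transport"
"k_b_MTR",0.1,"1/h","transport"
"k_f_acc",0.2,"1/h","transport"
"k_b_acc",0.02,"1/h","transport"
"k_f_loc",0.4,"1/h","transport"
"k_b_loc",0.2,"1/h","transport"
"k_OxysterolSynthesis",0.02,"1/h","transport"
"Km_CYP11A1",5000,"nmol/L","enzyme"
"Vmax_CYP11A1",4000,"nmol/L/h","enzyme"
"KmA_CYP17H",2500,"nmol/L","enzyme"
"KmB_CYP17H",1500,"nmol/L","enzyme"
"VmaxA_CYP17H",1600,"nmol/L/h","enzyme"
"VmaxB_CYP17H",800,"nmol/L/h","enzyme"
"KmA_CYP17L",1500,"nmol/L","enzyme"
"KmB_CYP17L",1500,"nmol/L","enzyme"
"VmaxA_CYP17L",250,"nmol/L/h","enzyme"
"VmaxB_CYP17L",700,"nmol/L/h","enzyme"
"KmA_HSD3B2",2500,"nmol/L","enzyme"
"KmB_HSD3B2",1500,"nmol/L","enzyme"
"KmC_HSD3B2",1500,"nmol/L","enzyme"
"VmaxA_HSD3B2",1600,"nmol/L/h","enzyme"
"VmaxB_HSD3B2",1200,"nmol/L/h","enzyme"
"VmaxC_HSD3B2",700,"nmol/L/h","enzyme"
"KmA_CYP21A2",2500,"nmol/L","enzyme"
"KmB_CYP21A2",2500,"nmol/L","enzyme"
"VmaxA_CYP21A2",2000,"nmol/L/h","enzyme"
"VmaxB_CYP21A2",1600,"nmol/L/h","enzyme"
"KmA_CYP11B1",2000,"nmol/L","enzyme"
"KmB_CYP11B1",2000,"nmol/L","enzyme"
"VmaxA_CYP11B1",1500,"nmol/L/h","enzyme"
"VmaxB_CYP11B1",1200,"nmol/L/h","enzyme"
"k_CYP11B2",0.001,"1/h","enzyme"
"KmA_HSD17B3",2000,"nmol/L","enzyme"
"KmB_HSD17B3",2000,"nmol/L","enzyme"
"VmaxA_HSD17B3",160,"nmol/L/h","enzyme"
"VmaxB_HSD17B3",40,"nmol/L/h","enzyme"
"KmA_CYP19A1",2000,"nmol/L","enzyme"
"KmB_CYP19A1",2000,"nmol/L","enzyme"
"VmaxA_CYP19A1",260,"nmol/L/h","enzyme"
"VmaxB_CYP19A1",30,"nmol/L/h","enzyme"
"k_diff_f_PREG",0.02,"1/h","diffusion"
"k_diff_f_HPREG",0.01,"1/h","diffusion"
"k_diff_f_DHEA",0.02,"1/h","diffusion"
"k_diff_f_PROG",0.01,"1/h","diffusion"
"k_diff_f_HPROG",0.01,"1/h","diffusion"
"k_diff_f_DIONE",0.02,"1/h","diffusion"
"k_diff_f_TESTO",0.05,"1/h","diffusion"
"k_diff_f_DCORTICO",0.04,"1/h","diffusion"
"k_diff_f_DCORT",0.04,"1/h","diffusion"
"k_diff_f_CORTICO",0.04,"1/h","diffusion"
"k_diff_f_CORT",0.04,"1/h","diffusion"
"k_diff_f_ALDO",0.04,"1/h","diffusion"
"k_diff_f_E1",0.05,"1/h","diffusion"
"k_diff_f_E2",0.05,"1/h","diffusion"
"k_diff_b_PREG",0.02,"1/h","diffusion"
"k_diff_b_HPREG",0.01,"1/h","diffusion"
"k_diff_b_DHEA",0.02,"1/h","diffusion"
"k_diff_b_PROG",0.01,"1/h","diffusion"
"k_diff_b_HPROG",0.01,"1/h","diffusion"
"k_diff_b_DIONE",0.02,"1/h","diffusion"
"k_diff_b_TESTO",0.05,"1/h","diffusion"
"k_diff_b_DCORTICO",0.04,"1/h","diffusion"
"k_diff_b_DCORT",0.04,"1/h","diffusion"
"k_diff_b_CORTICO",0.04,"1/h","diffusion"
"k_diff_b_CORT",0.04,"1/h","diffusion"
"k_diff_b_ALDO",0.04,"1/h","diffusion"
"k_diff_b_E1",0.05,"1/h","diffusion"
"k_diff_b_E2",0.05,"1/h","diffusion"
"k_dist_f",0.5,"1/h","distribution"
"k_dist_b",0.25,"1/h","distribution"
"n0",1e+06,"cells","proliferation"
"g_n",0.008,"1/h","proliferation"
"v0",2e-09,"mL","proliferation"
"g_v",0.002,"1/h","proliferation"
"v_med",2,"mL","proliferation"
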