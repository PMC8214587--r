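strategy,total_cost_chf,qalys,lys_discounted,lys_undiscounted,months_in_pfs,months_in_pd
chemotherapy,98794,1.04,1.76,1.86,7.17,15.10
pembrolizumab,155379,1.87,2.77,2.99,22.24,13.69
combination,236464,2.04,3.06,3.33,25.54,14.42
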