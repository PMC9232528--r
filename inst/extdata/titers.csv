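# 144-h terpene titers (mg/L, mean of biological triplicates) for the
# three strains. The squalene titer of the LD-number strain is not
# printed as a number; the 1.00 mg/L row is a SYNTHETIC intermediate
# placeholder (between WT and LD-size, consistent with the reported
# ordering) and is flagged in the synthetic column.
strain,lipid,time_h,titer_mg_per_l,sd,terbinafine,synthetic
WT,squalene,144,0.43,0.05,FALSE,FALSE
LD-size,squalene,144,13.93,0.50,FALSE,FALSE
LD-number,squalene,144,1.00,0.10,FALSE,TRUE
WT,zeaxanthin,144,1.27,0.10,FALSE,FALSE
LD-size,zeaxanthin,144,2.16,0.12,FALSE,FALSE
LD-number,zeaxanthin,144,2.85,0.15,FALSE,FALSE
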