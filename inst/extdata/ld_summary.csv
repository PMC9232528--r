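# Per-strain LD summary values as printed for the three yeast strains:
# wild type, the large-droplet strain (LD-size) and the many-droplet
# strain (LD-number). n_ld_per_cell for LD-size is 23 * 0.7 (a ~30%
# reduction from the WT count); diameters are the reported D_avg.
strain,n_ld_per_cell,d_avg_um
WT,23,0.20
LD-size,16.1,0.33
LD-number,51.67,0.20
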