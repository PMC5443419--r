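# per-tissue baseline optical properties for head-like phantoms
# synthetic: literature-plausible defaults, not fitted values; override via load_tissue_optics()
# units: mua_mm mm^-1, musp_mm mm^-1 (reduced scattering)
tissue,wavelength_nm,mua_mm,musp_mm
scalp,700,0.016875,0.85714
scalp,750,0.017437,0.8
scalp,800,0.018,0.75
scalp,850,0.018562,0.70588
scalp,900,0.019125,0.66667
scalp,950,0.019688,0.63158
scalp,1000,0.02025,0.6
skull,700,0.0114,1.0286
skull,750,0.0117,0.96
skull,800,0.012,0.9
skull,850,0.0123,0.84706
skull,900,0.0126,0.8
skull,950,0.0129,0.75789
skull,1000,0.0132,0.72
csf,700,0.0033906,0.28571
csf,750,0.0034453,0.26667
csf,800,0.0035,0.25
csf,850,0.0035547,0.23529
csf,900,0.0036094,0.22222
csf,950,0.0036641,0.21053
csf,1000,0.0037188,0.2
gm,700,0.01665,0.97143
gm,750,0.017325,0.90667
gm,800,0.018,0.85
gm,850,0.018675,0.8
gm,900,0.01935,0.75556
gm,950,0.020025,0.71579
gm,1000,0.0207,0.68
wm,700,0.014062,1.2571
wm,750,0.014531,1.1733
wm,800,0.015,1.1
wm,850,0.015469,1.0353
wm,900,0.015938,0.97778
wm,950,0.016406,0.92632
wm,1000,0.016875,0.88
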