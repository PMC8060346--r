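# Tissue composition constants for the Rodgers & Rowland tissue-to-plasma
# partitioning method, transcribed from the published compilation
# (Rodgers & Rowland, J Pharm Sci 95:1238-1257, 2006: fractional tissue
# water, neutral lipid and neutral phospholipid contents and albumin
# tissue-to-plasma ratios), with fractional organ volumes per kg body
# weight from standard reference-man values (Poulin & Theil compilation).
# f_ew/f_iw: extracellular/intracellular water volume fractions of tissue
# f_nl/f_np: neutral lipid / neutral phospholipid volume fractions
# ph_iw: intracellular water pH
# albumin_ratio: tissue-to-plasma albumin concentration ratio
# volume_frac: tissue volume, L per kg body weight
# The plasma and erythrocytes rows carry only volume_frac.
tissue,f_ew,f_iw,f_nl,f_np,ph_iw,albumin_ratio,volume_frac
adipose,0.135,0.017,0.790,0.0020,7.0,0.049,0.1857
bone,0.100,0.346,0.074,0.0011,7.0,0.100,0.0856
brain,0.162,0.620,0.051,0.0565,7.0,0.048,0.0200
gut,0.282,0.475,0.0487,0.0163,7.0,0.158,0.0171
heart,0.320,0.456,0.0115,0.0166,7.0,0.157,0.0047
kidney,0.273,0.483,0.0207,0.0162,7.0,0.130,0.0044
liver,0.161,0.573,0.0348,0.0252,7.0,0.086,0.0257
lung,0.336,0.446,0.0022,0.0128,7.0,0.212,0.0076
muscle,0.118,0.630,0.0238,0.0072,7.0,0.064,0.4000
skin,0.382,0.291,0.0284,0.0111,7.0,0.277,0.0371
spleen,0.207,0.579,0.0201,0.0198,7.0,0.097,0.0026
plasma,NA,NA,NA,NA,NA,NA,0.0424
erythrocytes,NA,NA,NA,NA,NA,NA,0.0347
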