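trait,level,unit,control_genotype,treatment_genotype,control_mean,treatment_mean,published_percent
length,organ,mm,W23xL317,dwarf3,353,141,-60
length,cell,um,W23xL317,dwarf3,147,152,3
width,organ,mm,W23xL317,dwarf3,23.3,24.2,4
width,cell,um,W23xL317,dwarf3,24.4,29.4,21
thickness,organ,um,W23xL317,dwarf3,94,111,18
thickness,cell,um,W23xL317,dwarf3,18.1,19.5,8
length_width,organ,ratio,W23xL317,dwarf3,14.8,5.6,-62
length_thickness,organ,ratio,W23xL317,dwarf3,4000,1300,-68
width_thickness,organ,ratio,W23xL317,dwarf3,250,220,-12
length,organ,mm,B104,UBI_GA20OX1,242,364,50
length,cell,um,B104,UBI_GA20OX1,134,138,3
width,organ,mm,B104,UBI_GA20OX1,15.7,13.2,-16
width,cell,um,B104,UBI_GA20OX1,23.6,19.7,-16
thickness,organ,um,B104,UBI_GA20OX1,113,96,-15
thickness,cell,um,B104,UBI_GA20OX1,18.5,17.3,-6
length_width,organ,ratio,B104,UBI_GA20OX1,13.3,23.4,76
length_thickness,organ,ratio,B104,UBI_GA20OX1,2200,3300,51
width_thickness,organ,ratio,B104,UBI_GA20OX1,140,140,0
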