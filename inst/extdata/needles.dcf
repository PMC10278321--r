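Record: needle
Name: 22G Pajunk Sprotte
Gauge: 22G
Length_mm: 90
Outer_diameter_mm: 0.72
Resistance_cm_s_per_ml: 667.9

Record: needle
Name: 22G Braun Spinocan
Gauge: 22G
Length_mm: 88
Outer_diameter_mm: 0.70
Resistance_cm_s_per_ml: 1411.3

Record: needle
Name: 22G M. Schilling
Gauge: 22G
Length_mm: 90
Outer_diameter_mm: 0.70
Resistance_cm_s_per_ml: 1028.7

Record: manometer
Bore_diameter_mm: 3.7

Record: fluid
Density_g_per_ml: 1.0006
Viscosity_mPa_s: 1.002
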