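# Consensus dosimetry dataset for the IR06 Pd-103 seed.
# Dose-rate constants in cGy.h-1.U-1; consensus = mean(exp, mc) in Perspex.
# g_table: Monte Carlo radial dose function in Perspex (line-source geometry,
# effective length 0.3 cm). F_table: dense Monte Carlo anisotropy function in
# Perspex. Sparse TLD-measured anisotropy points ship separately
# (ir06_anisotropy_tld.csv), as do the water and TLD g(r) columns
# (ir06_radial_dose.csv).

[source]
name = IR06-P103d
medium = perspex

[lambda]
unit = cGy.h-1.U-1
exp = 0.689
exp_sigma = 0.058
mc = 0.691
mc_sigma = 0.021
consensus = 0.690

[geometry]
unit = cm
physical_length = 0.47
active_length = 0.3
capsule_outer_diameter = 0.08
capsule_inner_diameter = 0.07
end_cap_thickness = 0.06
bead_count = 5
bead_diameter = 0.06
capsule_material = titanium
core_material = resin
core_mass_fractions = H:0.08,C:0.90,N:0.003,Cl:0.007,Pd:0.01

[nuclide]
name = Pd-103
half_life_days = 16.991

[g_table]
geometry_model = line
reference_radius_cm = 1.0
r_cm,g
0.5,1.448
1,1.000
1.5,0.817
2,0.668
3,0.422
4,0.264
5,0.156

[F_table]
r_cm,theta_0,theta_10,theta_20,theta_30,theta_40,theta_50,theta_60,theta_70,theta_80,theta_90
0.25,0.053,0.074,0.616,0.854,0.924,0.959,0.979,0.992,0.998,1.000
0.5,0.132,0.165,0.472,0.701,0.845,0.927,0.964,0.985,0.996,1.000
1,0.190,0.242,0.491,0.686,0.816,0.903,0.956,0.982,0.996,1.000
1.5,0.229,0.281,0.512,0.692,0.813,0.899,0.952,0.982,0.995,1.000
2,0.265,0.309,0.526,0.696,0.814,0.896,0.950,0.982,0.996,1.000
3,0.294,0.345,0.545,0.705,0.815,0.897,0.949,0.981,0.997,1.000
4,0.319,0.369,0.558,0.709,0.818,0.895,0.948,0.979,0.995,1.000
5,0.337,0.392,0.568,0.715,0.820,0.900,0.948,0.981,0.995,1.000
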