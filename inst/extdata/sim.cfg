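# Default gap-flow simulation configuration.
# Geometry: clinical-calibre coronary segment with a stent balloon nearly
# apposed to the wall after inflation (50 um initial annular gap).
# Fluid presets: "blood-analog" (default) or "water" (bench rig).

[geometry]
R_v_mm = 1.5
L_prox_mm = 20
L_bal_mm = 20
L_dist_mm = 20
n_x = 64

[fluid]
preset = blood-analog

[boundary]
P_in_mmHg = 120
P_out_mmHg = 20
# lumped distal resistance (mmHg s/mL); calibrated so the fully-open
# steady downstream wall shear stress sits in the physiological 1-2 Pa band
distal_resistance = 75

[profile]
# reference radial collapse speed of the balloon surface (mm/s)
vb_mm_s = 1.5
Rb_min_mm = 0.05
initial_gap_mm = 0.05
shoulder_frac = 0.05
shoulder_floor = 0.5

[protocol]
mode = rapid
start_pressure_atm = 16
slow_rate_atm_s = 2
rapid_duration_s = 1.5

[numerics]
dt_s = 0.001
gap_floor_mm = 0.01
settle_s = 0.1
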