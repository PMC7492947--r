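# Default two-arm trial specification: per-arm summary statistics of a
# randomized rapid- vs slow-balloon-deflation trial in STEMI (n = 105/106).
# continuous endpoints: name = mean, sd (natural units)
# binary endpoints / events: name = proportion (events: 30-day proportion)

[rapid]
n = 105

[rapid.continuous]
age = 62.9, 13.7
bmi = 24.7, 2.2
sbp = 125, 25
dbp = 76, 12
spo2 = 97.9, 1.9
hemoglobin = 135.7, 16.8
bnp = 190, 229
egfr = 59.5, 8.8
symptom_to_fmc_h = 4.6, 3.4
door_to_balloon_min = 74, 35
lesion_length_mm = 24.4, 9.3
proximal_ref_mm = 3.3, 0.5
distal_ref_mm = 3.1, 0.4
n_stents = 1.13, 0.34
inflation_atm = 16.2, 2.1
tfc_pre = 88, 23
tfc_prestent = 43, 18
tfc_post1 = 28, 9
tfc_post2 = 27, 9
ck_max = 4098, 3410
ckmb_max = 357, 236
tni_max = 65.3, 30.7
lvef = 50.1, 7.9

[rapid.binary]
male = 0.800000
hypertension = 0.590476
hyperlipidemia = 0.323810
diabetes = 0.190476
smoking = 0.523810
predilation = 0.876190
postdilation = 0.457143
thrombus_aspiration = 0.200000
tirofiban = 0.733333
ticagrelor = 0.257143
acei_arb = 0.876190
statins = 0.838095
beta_blockers = 0.857143
oral_anticoagulation = 0.028571
no_reflow = 0.076190

[rapid.artery]
LAD = 0.428571
LCX = 0.209524
RCA = 0.361905

[rapid.timi_pre]
grade0 = 0.752381
grade1 = 0.095238
grade2 = 0.076190
grade3 = 0.076190

[rapid.killip]
classI = 0.838095
classII = 0.152381
classIII = 0.009524
classIV = 0.000000

[rapid.events]
death = 0.028571
heart_failure = 0.057143
myocardial_infarction = 0.009524
revascularization = 0.009524
rehospitalization = 0.095238

[slow]
n = 106

[slow.continuous]
age = 61.2, 10.9
bmi = 24.4, 2.4
sbp = 124, 19
dbp = 75, 11
spo2 = 98.3, 1.7
hemoglobin = 137.5, 16.1
bnp = 160, 146
egfr = 60.4, 8.6
symptom_to_fmc_h = 4.1, 3.2
door_to_balloon_min = 77, 34
lesion_length_mm = 24.2, 9.5
proximal_ref_mm = 3.4, 0.4
distal_ref_mm = 3.2, 0.4
n_stents = 1.13, 0.34
inflation_atm = 16.1, 2.0
tfc_pre = 89, 24
tfc_prestent = 44, 22
tfc_post1 = 25, 8
tfc_post2 = 24, 7
ck_max = 2847, 2204
ckmb_max = 272, 212
tni_max = 52.4, 33.6
lvef = 51.9, 8.4

[slow.binary]
male = 0.867925
hypertension = 0.537736
hyperlipidemia = 0.264151
diabetes = 0.198113
smoking = 0.556604
predilation = 0.849057
postdilation = 0.396226
thrombus_aspiration = 0.226415
tirofiban = 0.688679
ticagrelor = 0.273585
acei_arb = 0.877358
statins = 0.811321
beta_blockers = 0.867925
oral_anticoagulation = 0.018868
no_reflow = 0.028302

[slow.artery]
LAD = 0.528302
LCX = 0.132075
RCA = 0.339623

[slow.timi_pre]
grade0 = 0.820755
grade1 = 0.018868
grade2 = 0.066038
grade3 = 0.094340

[slow.killip]
classI = 0.839623
classII = 0.141509
classIII = 0.018868
classIV = 0.000000

[slow.events]
death = 0.018868
heart_failure = 0.066038
myocardial_infarction = 0.000000
revascularization = 0.009434
rehospitalization = 0.084906

[enzyme]
peak_time_h = 12
sigma = 0.8
sample_times_h = 0, 6, 12, 18, 24, 48, 72
noise_sd = 0

[followup]
days = 30

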