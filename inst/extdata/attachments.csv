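muscle,pelvis_x,pelvis_y,femur_x,femur_y,note
iliopsoas,0.030,0.100,-0.010,0.040,synthetic sagittal coordinates; iliac fossa origin to lesser trochanter
gluteus_maximus,-0.060,-0.060,-0.030,0.060,synthetic; pelvis point is the ischial-tuberosity via point; femur point is the gluteal tuberosity
rectus_femoris,0.035,0.005,0.050,0.400,synthetic; anterior inferior iliac spine to patellar region of the thigh
hamstrings,-0.060,-0.060,-0.030,0.400,synthetic; ischial tuberosity to distal posterior thigh (toward tibial insertion)
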