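muscle,pcsa_mean,pcsa_sd,r_hip,r_knee,r_ankle,s_hip,s_knee,s_ankle,b_hip,a_hip,b_knee,a_knee,b_ankle,a_ankle
iliopsoas,28.9,6.9,0.022,0,0,-1,0,0,-0.17,-0.010,0,0,0,0
gluteus_maximus,46.8,8.7,0.027,0,0,1,0,0,0.17,0.010,0,0,0,0
vastus,157.4,31.5,0,0.044,0,0,1,0,0,0,0.18,0.011,0,0
rectus_femoris,34.8,7.4,0.014,0.044,0,-1,1,0,-0.10,-0.006,0.12,0.007,0,0
hamstrings,73.0,16.3,0.011,0.028,0,1,-1,0,0.10,0.006,-0.12,-0.007,0,0
tibialis_anterior,15.8,2.9,0,0,0.043,0,0,-1,0,0,0,0,-0.30,-0.018
soleus,124.1,24.9,0,0,0.026,0,0,1,0,0,0,0,0.30,0.018
gastrocnemius,73.1,16.0,0,0.022,0.031,0,-1,1,0,0,-0.10,-0.006,0.25,0.015
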