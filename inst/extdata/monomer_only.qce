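[cluster m1]
composition 1
energy 0
frequencies 1594.8 3656.7 3755.8
inertia 0.615 1.155 1.7699
mean_inertia 1.17996666667
sigma 2
volume 29.9
mass 18.0152
ion_pairs 0

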