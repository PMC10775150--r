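14
conf01 E=0
Rh      0.00000000     0.00000000     1.20000000
Rh      0.00000000     0.00000000    -1.20000000
C       2.94280904     0.00000000     0.94280904
C       3.88561808     0.00000000     1.88561808
C       4.82842712     0.00000000     2.82842712
C       0.00000000     2.94280904     0.94280904
C       0.00000000     3.88561808     1.88561808
C       0.00000000     4.82842712     2.82842712
C      -2.94280904     0.00000000     0.94280904
C      -3.88561808     0.00000000     1.88561808
C      -4.82842712     0.00000000     2.82842712
C      -0.00000000    -2.94280904     0.94280904
C      -0.00000000    -3.88561808     1.88561808
C      -0.00000000    -4.82842712     2.82842712
14
conf02 E=1.256512268
Rh      0.00000000     0.00000000     1.20000000
Rh      0.00000000     0.00000000    -1.20000000
C       2.97981520     0.40937869     0.87298758
C       3.97824170     0.54654643     1.74597516
C       4.97666820     0.68371417     2.61896274
C       0.08173803     2.86171317     1.01647206
C       0.10637410     3.72424166     2.03294411
C       0.13101017     4.58677016     3.04941617
C      -2.96679683     0.31961695     0.89977415
C      -3.94509964     0.42501081     1.79954830
C      -4.92340246     0.53040467     2.69932245
C      -0.33689079    -2.79044016     1.05855483
C      -0.43406163    -3.59529871     2.11710965
C      -0.53123248    -4.40015726     3.17566448
14
conf03 E=0.9026794883
Rh      0.00000000     0.00000000     1.20000000
Rh      0.00000000     0.00000000    -1.20000000
C       2.85583935    -0.26725663     1.01183137
C       3.72037929    -0.34816245     2.02366275
C       4.58491922    -0.42906827     3.03549412
C       0.03475025     3.04268743     0.83076281
C       0.04666018     4.08550529     1.66152562
C       0.05857010     5.12832315     2.49228843
C      -2.94257943     0.27049024     0.93047336
C      -3.89355549     0.35790666     1.86094672
C      -4.84453156     0.44532307     2.79142008
C      -0.22816049    -3.03701330     0.82737996
C      -0.30649000    -4.07964682     1.65475992
C      -0.38481951    -5.12228035     2.48213988
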