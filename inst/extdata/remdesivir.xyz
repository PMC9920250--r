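77
remdesivir generated conformer (synthetic stand-in geometry)
C      4.52552857     1.43879168    -1.18728736
C      4.26783840     1.54206800     0.30919519
C      5.20894972     0.66248080     1.16129287
C      6.70558083     0.98672087     0.98026789
C      7.10797928     2.41386637     1.32515751
C      4.80453941     0.73031909     2.64513672
O      3.48013918     0.20018236     2.83494175
C      3.40822275    -1.13942077     3.11287408
O      4.36842928    -1.88298258     3.25469160
C      1.93722540    -1.54465619     3.31466381
C      1.76463640    -3.05924036     3.32787441
N      1.05860382    -0.88289314     2.32439656
P      1.16325341    -1.35527599     0.75564458
O      2.56033519    -1.48180812     0.23383568
O      0.31797053    -0.26304588    -0.08498571
C     -1.01363518     0.05959234     0.27414496
C     -2.04639401    -0.60170402    -0.64379548
O     -3.33289720    -0.02230364    -0.33607122
C     -3.84867823     0.67104834    -1.50795026
C     -4.90029248    -0.14163794    -2.17741929
N     -5.71527045    -0.77615080    -2.71386244
C     -2.60188154     0.87240051    -2.40486111
O     -2.83828038     1.06756459    -3.79719948
C     -1.78827752    -0.37985927    -2.13217828
O     -2.33212849    -1.43845253    -2.93104448
C     -4.43143204     1.97450519    -1.01617192
C     -4.21267543     3.28483035    -1.42568661
C     -5.03477214     4.13109133    -0.64551582
C     -5.74589899     3.31604544     0.20478238
C     -6.73175553     3.56903197     1.20375317
N     -7.14817030     4.82210878     1.54978060
N     -7.25025962     2.55747176     1.82905195
C     -6.83943261     1.29193511     1.48692637
N     -5.94381944     0.97253434     0.60587008
N     -5.39741314     2.01950045    -0.03255362
O      0.27743941    -2.69052211     0.59359131
C      0.10134766    -3.38907037    -0.56795154
C      0.78668531    -3.13476905    -1.75389885
C      0.50303910    -3.88635696    -2.89726590
C     -0.46497929    -4.88856923    -2.85637630
C     -1.14602378    -5.14758637    -1.66909074
C     -0.85918665    -4.40144158    -0.52576243
H      5.49847394     1.85848963    -1.45825227
H      4.48967259     0.39716081    -1.52141027
H      3.76118481     1.99661897    -1.73802562
H      3.22801734     1.24510105     0.49037618
H      4.34050419     2.59156056     0.61686470
H      5.06594618    -0.37403370     0.82785357
H      7.00429339     0.77697780    -0.05338817
H      7.29340101     0.30080589     1.60352888
H      6.87627990     2.65752590     2.36583867
H      8.18743620     2.53809165     1.18908499
H      6.60955545     3.14070240     0.67767194
H      5.52755389     0.21048395     3.28500511
H      4.77343117     1.77001167     2.98884223
H      1.65296498    -1.16743371     4.30473033
H      2.31266118    -3.49823306     4.16923548
H      2.15414050    -3.52404419     2.41594733
H      0.71105201    -3.33674731     3.43888342
H      1.29623228     0.10645722     2.37124595
H     -1.11084778     1.15035199     0.22780726
H     -1.22779753    -0.20866722     1.31439881
H     -2.11413755    -1.66840297    -0.41752147
H     -2.01357806     1.72946268    -2.05321449
H     -2.98483626     0.17186771    -4.17185269
H     -0.73673002    -0.27495934    -2.41176330
H     -1.85969381    -2.26291050    -2.70309881
H     -3.54203416     3.60103644    -2.21688493
H     -5.11207311     5.20803436    -0.71786160
H     -6.46359550     5.56008861     1.45048953
H     -7.63895677     4.83729894     2.43656222
H     -7.33030689     0.46992929     2.03548985
H      1.55359330    -2.36884315    -1.82411988
H      1.04510911    -3.69331826    -3.82061205
H     -0.68125913    -5.47413286    -3.74707940
H     -1.89660815    -5.93363043    -1.63186978
H     -1.39323790    -4.60904360     0.39861066
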