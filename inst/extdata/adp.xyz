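22
adp generated conformer (synthetic stand-in geometry)
C      2.63379574     1.58881737    -0.38940375
C      1.66814621     0.65634617     0.28858366
O      1.40483337     0.73433341     1.48520277
N      1.07309514    -0.25362717    -0.55056979
C      0.06566307    -1.20260094    -0.06978428
C      0.06100230    -2.44357845    -0.95428998
C     -1.33570814    -0.54654632    -0.01566139
O     -2.32638424    -1.03053520    -0.55753373
N     -1.39000672     0.59620156     0.75813670
C     -2.63729348     1.25009985     1.05204800
H      3.52001871     1.70687278     0.24013851
H      2.15220507     2.55894088    -0.53626303
H      2.95306113     1.19634890    -1.35902811
H      1.07579738    -0.05261387    -1.54293213
H      0.32337266    -1.49935534     0.95452708
H      1.05012796    -2.91382062    -0.97014267
H     -0.20539032    -2.19453101    -1.98782183
H     -0.66169111    -3.18212541    -0.59150666
H     -0.58205048     0.79404497     1.34969099
H     -3.26865041     1.28260334     0.16013842
H     -3.14863430     0.69015519     1.83940424
H     -2.42530954     2.26456992     1.39706698
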