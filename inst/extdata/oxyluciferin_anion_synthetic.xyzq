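21 0 -1 1
synthetic oxyluciferin anion (distance-geometry + MMFF94 coordinates, Gasteiger-type charges normalized to net -1)
O          5.2896973818       0.2371674253       1.1392194909  -0.8724133736      0
C          4.1065308099       0.0646630659       0.7005237378  -0.1075550052      0
C          3.8428167082      -0.6070120259      -0.5046970162  -0.0679324082      0
C          2.5511975925      -0.8146661515      -1.0174200877  -0.0355178176      0
C          1.4447649460      -0.3330777820      -0.3032916017   0.0819956179      0
N          0.1111031345      -0.4566498467      -0.6738300646  -0.2337796579      0
C         -0.6551584293       0.1130615242       0.2337981501   0.1493540728      0
S          0.1630203953       0.8199589378       1.5648167572  -0.1117008902      0
C          1.6721867835       0.3372986625       0.8954531414   0.0543736134      0
C          2.9734581174       0.5354442042       1.3926655322  -0.0505691478      0
C         -2.0980464062       0.1600815293       0.1489571357   0.1364366457      0
N         -2.8820176476       0.7100349314       1.0199779886  -0.2028413396      0
C         -4.2087287260       0.6041916856       0.6812488635   0.2567469418      0
O         -5.1205781717       1.0559057155       1.3656506102  -0.2715991287      0
C         -4.4819256542      -0.1196581680      -0.6163118628   0.0811978881      0
S         -2.8610852839      -0.5847013921      -1.2419229183  -0.0931625437      0
H          4.6912439087      -0.9884889148      -1.0736154951   0.0617034226      0
H          2.4142670093      -1.3409413445      -1.9536747657   0.0645825465      0
H          3.1195037646       1.0634516096       2.3330047265   0.0631949364      0
H         -5.0877760949      -1.0080878221      -0.4239898547   0.0487428136      0
H         -4.9844741380       0.5520241564      -1.3160529640   0.0487428136      0
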