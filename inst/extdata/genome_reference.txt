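muscle gamma delta mu1 mu2 sigma1 sigma2
IL 0.66319536706936666 0.4965100221726199692 2.4731287474875900 4.37861917192583583 1.25034125242556304 1.73830938892665610
GMED 0.89981399819100216 0.2083410530161730057 6.0676246983288848 4.98071280737895261 0.74672970058905042 1.69562895165632010
VAS 0.74437547655411862 0.1244188887989184367 4.5209173790804051 6.27844438838844443 0.96330864460384769 0.11611962176743890
TA 0.96645839696261393 0.7790967883442243558 4.8932318672417319 1.73388901943204843 1.84777967514008012 1.37181876423641125
SOL 0.21076894902011173 0.9458392424024539835 2.6279057596167048 3.44657226833815233 0.88678566121368330 1.67371124584634678
RF 0.68517600161451564 0.0014134145542549787 3.4722031329972403 1.32516818297313765 0.62246392736883660 2.00000000000000000
BIFl 0.97657391832369467 0.0086723001469093692 0.4619760135362122 5.70202488356019721 1.37334968076352215 0.84882863279512832
GAS 0.55411529492797695 0.0620834951352187969 5.3617602497991781 0.37131632412538917 0.44201682327377734 1.29788646068296165
EDL 0.26064932783326367 0.1781697908499733085 4.8716207051701037 5.43838848727783297 0.40361801564900801 1.79051807853672651
FDL 0.73744000897593742 0.9662318732170205315 3.7188580368423105 2.32240406415952627 0.45671115984272476 1.78164014903255685
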