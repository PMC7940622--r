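muscle gamma delta mu1 mu2 sigma1 sigma2
IL 0.60894098551129605 0.443793884856882592 2.37057884700476151 4.45413537708044149 1.31690211522735878 1.78817231966325685
GMED 0.80004303633762985 0.218837349851393248 5.66947290328185538 4.74589202198001203 0.84206173396707007 1.66047952083238770
VAS 0.72671238327761534 0.112095373410027441 5.57347350547783815 6.28318530717958623 0.94603793924618096 0.16183403696967996
TA 0.93889475430996450 0.820045677780475435 5.29719102605511161 2.03703495791435829 1.65878479782690080 1.26853291084036157
SOL 0.29819131198806342 0.994170204514649325 2.97196429768636605 3.69970021063721477 0.89907980759595318 1.63485648382473703
RF 0.63462643196106971 0.096930318827983739 3.80229088603225263 1.51789880760499818 0.73090453460313498 1.98271017114946946
BIFl 1.00000000000000000 0.013819980106206947 0.74419626425588747 5.57312477475812873 1.52891885192901245 0.79185890217434329
GAS 0.51620943607994840 0.050113770403056826 5.06295877550703910 0.91359516552731634 0.59398433579531063 1.31363784493694302
EDL 0.24354150867861227 0.117616667114783649 5.13127006695854782 4.79006037896670023 0.72692877077966078 1.86782814861345603
FDL 0.63363659795760741 0.994649402696773488 3.80441251910321965 2.17663685413849350 0.38706804067113731 1.76864496159462292
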