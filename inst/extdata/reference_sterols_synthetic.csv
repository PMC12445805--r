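name,formula,expected_rt,bring_class
ergosterol,C28H44O,4.6,NA
desmosterol,C27H44O,4.9,D5
24-methylenecholesterol,C28H46O,5.0,D5
brassicasterol,C28H46O,5.2,D5
anthelsterol,C28H44O,5.3,NA
cholesterol,C27H46O,5.55,D5
episterol,C28H46O,6.0,D7
stigmasterol,C29H48O,6.1,D5
campesterol,C28H48O,6.3,D5
spinasterol,C29H48O,6.45,D7
isofucosterol,C29H48O,6.6,D5
lophenol,C28H48O,6.75,D7
avenasterol,C29H48O,6.85,D5
beta-sitosterol,C29H50O,7.1,D5
schottenol,C29H50O,7.3,D7
sitostanol,C29H52O,7.6,D0
cycloeucalenol,C30H50O,7.9,CPR
cycloartenol,C30H50O,8.2,CPR
agnosterol,C30H48O,8.5,D8
cyclolaudenol,C31H52O,8.8,CPR
24-methylenecycloartanol,C31H52O,9.1,CPR
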