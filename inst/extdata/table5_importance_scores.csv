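measure,feature,score
mda,bmi,19.3095
mda,size,9.6143
mda,asa,5.7061
mda,hypertension,4.6416
mda,ctvalue,4.6293
mda,prevma,1.3311
mda,preblood,0.8616
mda,arrhythmia,0.2419
mda,dm,0.0276
mda,age,-0.4422
mdg,bmi,16.688
mdg,size,12.2722
mdg,prevma,9.5934
mdg,ctvalue,9.3884
mdg,age,8.0945
mdg,hypertension,2.9614
mdg,asa,2.3838
mdg,preblood,1.5554
mdg,dm,1.2103
mdg,arrhythmia,0.3524
relief,ctvalue,-2.8871
relief,prevma,-3.3417
relief,arrhythmia,-4.4444
relief,age,-4.6933
relief,bmi,-6.7295
relief,size,-9.2895
relief,asa,-13.3596
relief,preblood,-19.3992
relief,hypertension,-22.7188
relief,dm,-23.1212
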