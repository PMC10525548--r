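category,keyword,frequency
exam_type,ct,12752
exam_type,scan,9651
exam_type,tomography,8043
exam_type,radiograph,7198
exam_type,xray,5357
exam_type,mri,4943
exam_type,contrast,4140
exam_type,resonance,3318
exam_type,magnetic,3310
exam_type,abdominal,3274
exam_type,ultrasound,2198
exam_type,angiography,1680
exam_type,angiogram,1220
exam_type,catheter,1020
body_part,chest,6881
body_part,artery,4718
body_part,abdomen,2856
body_part,lobe,2780
body_part,lung,2728
body_part,bone,2654
body_part,tissue,2277
body_part,mouth,2235
body_part,pulmonary,2100
body_part,head,2092
body_part,brain,2038
body_part,vein,1897
body_part,liver,1695
body_part,ventricle,1675
body_part,pelvi,1635
body_part,kidney,1468
body_part,spine,1321
body_part,neck,1307
body_part,pleural,1294
body_part,muscle,1293
body_part,renal,1266
body_part,coronary,1258
body_part,femoral,1252
body_part,cervical,1196
body_part,atrium,1192
body_part,bowel,1171
body_part,aorta,1098
body_part,aortic,1064
body_part,hip,1018
body_part,heart,620
body_part,tooth,619
problem,tumor,2387
problem,fracture,2162
problem,normal,2083
problem,cystic,1700
problem,cyst,1477
problem,effusion,1371
problem,calcification,1179
problem,nodule,1158
problem,hepatic,997
problem,node,981
problem,stent,901
problem,heterogeneous,889
problem,pancreatic,874
problem,weak,858
problem,aneurysm,842
problem,edema,833
problem,irregular,752
problem,dilatation,746
problem,absces,745
problem,disease,743
problem,apical,700
problem,hematoma,688
problem,fistula,608
problem,cancer,505
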