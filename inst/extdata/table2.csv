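exam_type,body_part,problem,n_images
ct,chest,tumor,52
ct,artery,aneurysm,63
ct,abdomen,tumor,38
ct,abdomen,cystic,58
ct,abdomen,hepatic,47
ct,abdomen,pancreatic,35
ct,abdomen,hematoma,38
ct,lobe,hepatic,51
ct,lung,effusion,56
ct,head,pancreatic,56
ct,vein,hepatic,34
ct,liver,cyst,35
ct,liver,hepatic,28
scan,chest,nodule,77
scan,abdomen,cystic,23
scan,lobe,hepatic,18
scan,lung,effusion,18
scan,lung,nodule,41
scan,pulmonary,nodule,17
scan,head,pancreatic,13
tomography,chest,tumor,29
tomography,lobe,nodule,41
tomography,lobe,hepatic,21
tomography,lung,effusion,20
tomography,lung,nodule,34
tomography,pulmonary,nodule,21
radiograph,chest,normal,47
radiograph,bone,fracture,41
radiograph,pelvi,fracture,44
radiograph,neck,fracture,31
radiograph,femoral,fracture,31
radiograph,hip,fracture,32
xray,chest,normal,65
contrast,artery,aneurysm,32
abdominal,aortic,aneurysm,35
angiography,artery,normal,39
angiogram,artery,aneurysm,58
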