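rank,feature,algorithm,mean_acc,sd_acc,max_acc,min_acc
1,minimal_lumen_diameter,svm_rbf,63.43,6.46,71.57,53.92
2,proximal_radius_rapport,svm_poly,64.31,5.14,71.57,53.92
3,radius_rapport,svm_poly,65.59,4.39,71.57,54.9
4,percentage_diameter_reduction,svm_poly,66.18,1.4,68.63,63.73
5,mean_lumen_radius,tree,62.75,6.75,71.57,53.92
6,minimum_lumen_radius,nbayes,60.59,6.06,71.57,53.92
7,weight,nbayes,64.51,4.27,69.61,53.92
8,mean_lumen_radius_stenosis,svm_rbf,67.35,2.01,71.57,64.71
9,mean_radius_per_length,svm_rbf,61.76,6,71.57,53.92
10,maximum_radius_rapport,knn5,64.31,5.79,71.57,53.92
11,stenosis_lesion_length,svm_poly,66.27,1.53,68.63,63.73
12,ht,tree,62.25,6.59,71.57,53.92
13,ivs,svm_rbf,64.61,4.54,71.57,53.92
14,maximum_lumen_radius,adaboost,65.39,2.98,69.61,58.82
15,smoking,svm_rbf,55.5,4.8,59.8,47.52
16,dyslipidemia,nbayes,54.71,6.51,60.54,43.88
17,aht,svm_rbf,53.53,3.72,56.86,47.34
18,diastolic_pattern,nbayes,52.88,4.44,56.86,45.5
19,age,svm_linear,51.17,3.64,54.43,45.11
20,diabetes,rf60,50.33,4.01,53.92,43.66
21,distal_area,tree,50.53,3.79,53.92,44.22
22,echo_ef,svm_poly,49.59,4.83,53.92,41.56
23,hb,svm_linear,48.72,5.8,53.92,39.06
24,height,rf60,51.43,2.78,53.92,46.8
25,proximal_area,svm_linear,50.52,3.8,53.92,44.2
26,sex,svm_linear,48.59,5.94,53.92,38.7
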