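phase,group,subgroup,n,mean_pdt,sd_pdt
1,patient,junior,30,27.86,17.01
1,patient,senior,31,23.30,11.7
1,monitoring_equipment,junior,30,1.66,4.51
1,monitoring_equipment,senior,31,1.15,2.08
1,documentation,junior,30,59.73,17.59
1,documentation,senior,31,59.97,14.51
1,medication_general_equipment,junior,30,3.22,4.42
1,medication_general_equipment,senior,31,4.28,5.75
1,excluded,junior,30,7.52,4.56
1,excluded,senior,31,11.30,6.3
2,patient,junior,30,14.47,10.31
2,patient,senior,31,13.46,8.78
2,monitoring_equipment,junior,30,25.17,10.82
2,monitoring_equipment,senior,31,21.95,12.25
2,documentation,junior,30,1.07,3.03
2,documentation,senior,31,2.94,5.91
2,medication_general_equipment,junior,30,48.77,18.05
2,medication_general_equipment,senior,31,48.37,15.72
2,excluded,junior,30,10.52,7.15
2,excluded,senior,31,13.29,7.39
3,patient,junior,30,53.98,16.59
3,patient,senior,31,48.35,15.73
3,monitoring_equipment,junior,30,16.46,10.33
3,monitoring_equipment,senior,31,16.5,10.89
3,documentation,junior,30,1.61,6.16
3,documentation,senior,31,1.07,2.16
3,medication_general_equipment,junior,30,18.10,10.32
3,medication_general_equipment,senior,31,21.26,9.31
3,excluded,junior,30,9.86,7.13
3,excluded,senior,31,12.83,7.7
4,patient,junior,30,44.85,16.72
4,patient,senior,31,50.22,17.71
4,monitoring_equipment,junior,30,33.93,13.02
4,monitoring_equipment,senior,31,23.32,15.45
4,documentation,junior,30,0.10,0.34
4,documentation,senior,31,0.28,0.71
4,medication_general_equipment,junior,30,13.93,7.22
4,medication_general_equipment,senior,31,13.63,7.84
4,excluded,junior,30,7.19,5.42
4,excluded,senior,31,12.55,12.07
5,patient,junior,30,92.43,5.86
5,patient,senior,31,90.90,7.78
5,monitoring_equipment,junior,30,0.53,1.25
5,monitoring_equipment,senior,31,0.64,2.76
5,documentation,junior,30,0,0
5,documentation,senior,31,0,0
5,medication_general_equipment,junior,30,5.96,5.11
5,medication_general_equipment,senior,31,6.25,5.07
5,excluded,junior,30,1.09,1.36
5,excluded,senior,31,2.20,3.39
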