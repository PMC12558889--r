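year,province,city,category,count
2014,Jiangsu,,health_technician,45.85
2014,Jiangsu,,licensed_physician,17.86
2014,Jiangsu,,registered_nurse,18.88
2014,Jiangsu,,pharmacist,2.55
2014,Jiangsu,,other_health_technician,2
2015,Jiangsu,,health_technician,48.7
2015,Jiangsu,,licensed_physician,18.92
2015,Jiangsu,,registered_nurse,20.4
2015,Jiangsu,,pharmacist,2.78
2015,Jiangsu,,other_health_technician,2.08
2016,Jiangsu,,health_technician,51.7
2016,Jiangsu,,licensed_physician,20.46
2016,Jiangsu,,registered_nurse,22.12
2016,Jiangsu,,pharmacist,2.78
2016,Jiangsu,,other_health_technician,2.52
2017,Jiangsu,,health_technician,54.77
2017,Jiangsu,,licensed_physician,21.71
2017,Jiangsu,,registered_nurse,23.69
2017,Jiangsu,,pharmacist,2.88
2017,Jiangsu,,other_health_technician,2.95
2018,Jiangsu,,health_technician,59.01
2018,Jiangsu,,licensed_physician,23.33
2018,Jiangsu,,registered_nurse,26.04
2018,Jiangsu,,pharmacist,3.02
2018,Jiangsu,,other_health_technician,3.19
2019,Jiangsu,,health_technician,63.33
2019,Jiangsu,,licensed_physician,25.47
2019,Jiangsu,,registered_nurse,27.98
2019,Jiangsu,,pharmacist,3.15
2019,Jiangsu,,other_health_technician,3.47
2020,Jiangsu,,health_technician,66.55
2020,Jiangsu,,licensed_physician,26.78
2020,Jiangsu,,registered_nurse,29.42
2020,Jiangsu,,pharmacist,3.26
2020,Jiangsu,,other_health_technician,3.72
2021,Jiangsu,,health_technician,69.18
2021,Jiangsu,,licensed_physician,27.27
2021,Jiangsu,,registered_nurse,30.87
2021,Jiangsu,,pharmacist,3.43
2021,Jiangsu,,other_health_technician,4.32
2022,Jiangsu,,health_technician,71.37
2022,Jiangsu,,licensed_physician,27.92
2022,Jiangsu,,registered_nurse,31.83
2022,Jiangsu,,pharmacist,3.57
2022,Jiangsu,,other_health_technician,4.21
2014,Zhejiang,,health_technician,37.59
2014,Zhejiang,,licensed_physician,14.57
2014,Zhejiang,,registered_nurse,14.51
2014,Zhejiang,,pharmacist,2.45
2014,Zhejiang,,other_health_technician,1.81
2015,Zhejiang,,health_technician,40.56
2015,Zhejiang,,licensed_physician,15.81
2015,Zhejiang,,registered_nurse,15.99
2015,Zhejiang,,pharmacist,2.58
2015,Zhejiang,,other_health_technician,1.88
2016,Zhejiang,,health_technician,43.26
2016,Zhejiang,,licensed_physician,16.82
2016,Zhejiang,,registered_nurse,17.45
2016,Zhejiang,,pharmacist,2.69
2016,Zhejiang,,other_health_technician,2.04
2017,Zhejiang,,health_technician,45.97
2017,Zhejiang,,licensed_physician,17.87
2017,Zhejiang,,registered_nurse,18.77
2017,Zhejiang,,pharmacist,2.79
2017,Zhejiang,,other_health_technician,2.22
2018,Zhejiang,,health_technician,48.62
2018,Zhejiang,,licensed_physician,19.08
2018,Zhejiang,,registered_nurse,20.15
2018,Zhejiang,,pharmacist,2.9
2018,Zhejiang,,other_health_technician,2.48
2019,Zhejiang,,health_technician,52.02
2019,Zhejiang,,licensed_physician,20.55
2019,Zhejiang,,registered_nurse,21.98
2019,Zhejiang,,pharmacist,3.03
2019,Zhejiang,,other_health_technician,2.67
2020,Zhejiang,,health_technician,54.8
2020,Zhejiang,,licensed_physician,21.77
2020,Zhejiang,,registered_nurse,23.31
2020,Zhejiang,,pharmacist,3.14
2020,Zhejiang,,other_health_technician,2.74
2021,Zhejiang,,health_technician,57.91
2021,Zhejiang,,licensed_physician,23.27
2021,Zhejiang,,registered_nurse,25.03
2021,Zhejiang,,pharmacist,3.25
2021,Zhejiang,,other_health_technician,2.87
2022,Zhejiang,,health_technician,61.28
2022,Zhejiang,,licensed_physician,24.66
2022,Zhejiang,,registered_nurse,26.7
2022,Zhejiang,,pharmacist,3.3
2022,Zhejiang,,other_health_technician,2.91
2014,Shanghai,,health_technician,16.41
2014,Shanghai,,licensed_physician,6.12
2014,Shanghai,,registered_nurse,7.19
2014,Shanghai,,pharmacist,0.92
2014,Shanghai,,other_health_technician,0.99
2015,Shanghai,,health_technician,17.01
2015,Shanghai,,licensed_physician,6.3
2015,Shanghai,,registered_nurse,7.54
2015,Shanghai,,pharmacist,0.95
2015,Shanghai,,other_health_technician,1.02
2016,Shanghai,,health_technician,17.82
2016,Shanghai,,licensed_physician,6.54
2016,Shanghai,,registered_nurse,7.94
2016,Shanghai,,pharmacist,0.98
2016,Shanghai,,other_health_technician,1.07
2017,Shanghai,,health_technician,18.69
2017,Shanghai,,licensed_physician,6.79
2017,Shanghai,,registered_nurse,8.39
2017,Shanghai,,pharmacist,1
2017,Shanghai,,other_health_technician,1.15
2018,Shanghai,,health_technician,19.56
2018,Shanghai,,licensed_physician,7.16
2018,Shanghai,,registered_nurse,8.8
2018,Shanghai,,pharmacist,1.02
2018,Shanghai,,other_health_technician,1.16
2019,Shanghai,,health_technician,20.45
2019,Shanghai,,licensed_physician,7.47
2019,Shanghai,,registered_nurse,9.29
2019,Shanghai,,pharmacist,1.04
2019,Shanghai,,other_health_technician,1.17
2020,Shanghai,,health_technician,21.44
2020,Shanghai,,licensed_physician,7.84
2020,Shanghai,,registered_nurse,9.72
2020,Shanghai,,pharmacist,1.07
2020,Shanghai,,other_health_technician,1.17
2021,Shanghai,,health_technician,22.9
2021,Shanghai,,licensed_physician,8.41
2021,Shanghai,,registered_nurse,10.39
2021,Shanghai,,pharmacist,1.12
2021,Shanghai,,other_health_technician,1.28
2022,Shanghai,,health_technician,23.6
2022,Shanghai,,licensed_physician,8.6
2022,Shanghai,,registered_nurse,10.64
2022,Shanghai,,pharmacist,1.13
2022,Shanghai,,other_health_technician,1.32
2014,Anhui,,health_technician,26.8
2014,Anhui,,licensed_physician,10.37
2014,Anhui,,registered_nurse,11.5
2014,Anhui,,pharmacist,1.29
2014,Anhui,,other_health_technician,1.39
2015,Anhui,,health_technician,28.08
2015,Anhui,,licensed_physician,10.78
2015,Anhui,,registered_nurse,11.93
2015,Anhui,,pharmacist,1.35
2015,Anhui,,other_health_technician,1.44
2016,Anhui,,health_technician,29.37
2016,Anhui,,licensed_physician,11.27
2016,Anhui,,registered_nurse,12.64
2016,Anhui,,pharmacist,1.39
2016,Anhui,,other_health_technician,1.47
2017,Anhui,,health_technician,31.35
2017,Anhui,,licensed_physician,12.08
2017,Anhui,,registered_nurse,13.81
2017,Anhui,,pharmacist,1.45
2017,Anhui,,other_health_technician,1.51
2018,Anhui,,health_technician,33.36
2018,Anhui,,licensed_physician,12.68
2018,Anhui,,registered_nurse,14.97
2018,Anhui,,pharmacist,1.5
2018,Anhui,,other_health_technician,1.65
2019,Anhui,,health_technician,36.12
2019,Anhui,,licensed_physician,13.84
2019,Anhui,,registered_nurse,16.34
2019,Anhui,,pharmacist,1.57
2019,Anhui,,other_health_technician,1.8
2020,Anhui,,health_technician,41.21
2020,Anhui,,licensed_physician,16.42
2020,Anhui,,registered_nurse,18.82
2020,Anhui,,pharmacist,1.67
2020,Anhui,,other_health_technician,1.88
2021,Anhui,,health_technician,43.51
2021,Anhui,,licensed_physician,17.26
2021,Anhui,,registered_nurse,20.1
2021,Anhui,,pharmacist,1.71
2021,Anhui,,other_health_technician,2.1
2022,Anhui,,health_technician,47.12
2022,Anhui,,licensed_physician,18.6
2022,Anhui,,registered_nurse,22.14
2022,Anhui,,pharmacist,1.71
2022,Anhui,,other_health_technician,2.01
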