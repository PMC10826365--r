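group,age_group,activity,mode,condition,m_net,m_net_sd,vo2,vo2_sd,mets,sr,bml
older-MinAct,older,MinAct,P_crit,34,75.5,9.4,0.43,0.08,1.64,77.2,0.38
older-MinAct,older,MinAct,P_crit,36,80.7,14.5,0.41,0.10,1.74,84.3,0.37
older-MinAct,older,MinAct,P_crit,38,82.4,17.6,0.48,0.16,1.73,89.3,0.39
older-MinAct,older,MinAct,P_crit,40,84.4,15.1,0.47,0.13,1.86,90.4,0.41
older-MinAct,older,MinAct,T_crit,16,78.7,15.8,0.45,0.13,1.67,82.6,0.33
older-MinAct,older,MinAct,T_crit,12,77.8,10.0,0.43,0.09,1.71,92.0,0.38
young-MinAct,young,MinAct,P_crit,34,85.7,9.4,0.50,0.07,1.72,121.8,0.54
young-MinAct,young,MinAct,P_crit,36,78.0,13.5,0.42,0.10,1.72,136.4,0.60
young-MinAct,young,MinAct,P_crit,38,81.9,13.5,0.47,0.10,1.70,202.4,0.94
young-MinAct,young,MinAct,P_crit,40,80.1,8.7,0.46,0.09,1.76,167.1,0.89
young-MinAct,young,MinAct,T_crit,16,85.5,10.8,0.48,0.09,1.86,141.7,0.62
young-MinAct,young,MinAct,T_crit,12,88.9,10.6,0.51,0.11,1.93,185.8,0.77
older-Rest,older,Rest,P_crit,34,48.4,9.5,0.27,0.06,1.13,44.6,0.19
older-Rest,older,Rest,P_crit,36,46.8,7.4,0.25,0.05,1.05,57.7,0.27
older-Rest,older,Rest,P_crit,38,50.2,9.6,0.30,0.08,1.05,68.2,0.35
older-Rest,older,Rest,P_crit,40,49.8,8.0,0.28,0.08,1.14,65.5,0.31
older-Rest,older,Rest,T_crit,16,52.5,9.3,0.30,0.08,1.16,51.6,0.22
older-Rest,older,Rest,T_crit,12,51.5,9.1,0.29,0.07,1.12,52.2,0.26
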