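group,age_group,activity,mode,condition,t_db,t_db_lo,t_db_hi,p_a,p_a_lo,p_a_hi,rh,rh_lo,rh_hi
older-MinAct,older,MinAct,P_crit,34,33.9,33.7,34.0,25.6,22.6,28.6,62.1,52.8,71.4
older-MinAct,older,MinAct,P_crit,36,36.2,36.0,36.4,24.1,21.7,26.5,53.5,48.2,58.8
older-MinAct,older,MinAct,P_crit,38,38.0,37.8,38.3,23.0,20.6,25.5,46.1,41.7,50.6
older-MinAct,older,MinAct,P_crit,40,40.2,40.0,40.3,19.0,16.3,21.7,34.0,29.2,38.8
older-MinAct,older,MinAct,T_crit,16,40.3,38.4,42.2,15.9,15.6,16.2,28.6,25.8,31.5
older-MinAct,older,MinAct,T_crit,12,42.9,40.9,44.8,11.9,11.6,12.2,18.8,17.0,20.5
young-MinAct,young,MinAct,P_crit,34,33.9,33.7,34.2,31.7,30.9,32.5,79.7,77.6,81.7
young-MinAct,young,MinAct,P_crit,36,36.0,35.9,36.1,29.6,28.6,30.7,66.5,64.1,69.0
young-MinAct,young,MinAct,P_crit,38,38.1,37.8,38.4,29.7,27.8,31.6,59.5,55.5,63.6
young-MinAct,young,MinAct,P_crit,40,40.0,39.9,40.1,28.2,26.6,29.7,51.0,48.2,53.8
young-MinAct,young,MinAct,T_crit,16,46.4,45.5,47.3,16.3,16.0,16.5,20.7,19.9,21.5
young-MinAct,young,MinAct,T_crit,12,49.3,48.2,50.4,12.2,12.0,12.4,13.8,12.9,14.7
older-Rest,older,Rest,P_crit,34,33.9,33.7,34.1,26.4,22.7,30.2,66.5,55.9,77.1
older-Rest,older,Rest,P_crit,36,36.2,35.9,36.4,26.4,24.4,28.4,59.1,54.6,63.5
older-Rest,older,Rest,P_crit,38,38.1,37.9,38.3,26.7,24.2,29.3,53.4,48.4,58.5
older-Rest,older,Rest,P_crit,40,40.1,40.0,40.1,21.6,19.3,24.0,38.8,34.5,43.1
older-Rest,older,Rest,T_crit,16,44.1,41.8,46.4,16.1,15.6,16.5,24.0,21.2,26.8
older-Rest,older,Rest,T_crit,12,46.1,44.1,48.1,11.5,11.2,11.9,15.6,13.7,17.5
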