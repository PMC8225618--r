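"subject_id","disease_group","unit","epcam_status","transcript","copies"
"P01","mCRPC","bulk_CTC",NA,"AR-FL",0.5
"P02","mCRPC","bulk_CTC",NA,"AR-FL",1
"P03","mCRPC","bulk_CTC",NA,"AR-FL",1.5
"P04","mCRPC","bulk_CTC",NA,"AR-FL",2
"P05","mCRPC","bulk_CTC",NA,"AR-FL",2.5
"P06","mCRPC","bulk_CTC",NA,"AR-FL",3
"P07","mCRPC","bulk_CTC",NA,"AR-FL",4
"P08","mCRPC","bulk_CTC",NA,"AR-FL",5
"P09","mCRPC","bulk_CTC",NA,"AR-FL",6
"P10","mCRPC","bulk_CTC",NA,"AR-FL",7
"P11","mCRPC","bulk_CTC",NA,"AR-FL",8
"P12","mCRPC","bulk_CTC",NA,"AR-FL",8.5
"P13","mCRPC","bulk_CTC",NA,"AR-FL",9
"P14","mCRPC","bulk_CTC",NA,"AR-FL",0
"P15","mCRPC","bulk_CTC",NA,"AR-FL",10
"P16","mCRPC","bulk_CTC",NA,"AR-FL",11
"P17","mCRPC","bulk_CTC",NA,"AR-FL",12
"P18","mCRPC","bulk_CTC",NA,"AR-FL",13
"P19","mCRPC","bulk_CTC",NA,"AR-FL",14
"P20","mCRPC","bulk_CTC",NA,"AR-FL",15
"P21","mCRPC","bulk_CTC",NA,"AR-FL",16
"P22","mCRPC","bulk_CTC",NA,"AR-FL",18
"P23","mCRPC","bulk_CTC",NA,"AR-FL",20
"P24","mCRPC","bulk_CTC",NA,"AR-FL",25
"P25","mCRPC","bulk_CTC",NA,"AR-FL",91.46
"P26","mCRPC","bulk_CTC",NA,"AR-FL",250
"P27","mCRPC","bulk_CTC",NA,"AR-FL",280
"P28","mCRPC","bulk_CTC",NA,"AR-FL",0
"P29","mCRPC","bulk_CTC",NA,"AR-FL",0
"P01","mCRPC","bulk_CTC",NA,"AR-V7",0.2
"P02","mCRPC","bulk_CTC",NA,"AR-V7",0.4
"P03","mCRPC","bulk_CTC",NA,"AR-V7",0.6
"P04","mCRPC","bulk_CTC",NA,"AR-V7",0.8
"P05","mCRPC","bulk_CTC",NA,"AR-V7",1.3
"P06","mCRPC","bulk_CTC",NA,"AR-V7",2
"P07","mCRPC","bulk_CTC",NA,"AR-V7",2.5
"P08","mCRPC","bulk_CTC",NA,"AR-V7",3
"P09","mCRPC","bulk_CTC",NA,"AR-V7",3.5
"P10","mCRPC","bulk_CTC",NA,"AR-V7",4
"P11","mCRPC","bulk_CTC",NA,"AR-V7",4.5
"P12","mCRPC","bulk_CTC",NA,"AR-V7",5
"P13","mCRPC","bulk_CTC",NA,"AR-V7",6
"P14","mCRPC","bulk_CTC",NA,"AR-V7",7
"P15","mCRPC","bulk_CTC",NA,"AR-V7",8
"P16","mCRPC","bulk_CTC",NA,"AR-V7",10
"P17","mCRPC","bulk_CTC",NA,"AR-V7",11.16
"P18","mCRPC","bulk_CTC",NA,"AR-V7",12
"P19","mCRPC","bulk_CTC",NA,"AR-V7",70
"P20","mCRPC","bulk_CTC",NA,"AR-V7",0
"P21","mCRPC","bulk_CTC",NA,"AR-V7",0
"P22","mCRPC","bulk_CTC",NA,"AR-V7",0
"P23","mCRPC","bulk_CTC",NA,"AR-V7",0
"P24","mCRPC","bulk_CTC",NA,"AR-V7",0
"P25","mCRPC","bulk_CTC",NA,"AR-V7",0
"P26","mCRPC","bulk_CTC",NA,"AR-V7",0
"P27","mCRPC","bulk_CTC",NA,"AR-V7",0
"P28","mCRPC","bulk_CTC",NA,"AR-V7",0
"P29","mCRPC","bulk_CTC",NA,"AR-V7",0
"P01","mCRPC","bulk_CTC",NA,"AR-v567es",0.14
"P02","mCRPC","bulk_CTC",NA,"AR-v567es",0.2
"P03","mCRPC","bulk_CTC",NA,"AR-v567es",0.3
"P04","mCRPC","bulk_CTC",NA,"AR-v567es",0.5
"P05","mCRPC","bulk_CTC",NA,"AR-v567es",0.7
"P06","mCRPC","bulk_CTC",NA,"AR-v567es",1
"P07","mCRPC","bulk_CTC",NA,"AR-v567es",1.2
"P08","mCRPC","bulk_CTC",NA,"AR-v567es",1.5
"P09","mCRPC","bulk_CTC",NA,"AR-v567es",2
"P10","mCRPC","bulk_CTC",NA,"AR-v567es",2.5
"P11","mCRPC","bulk_CTC",NA,"AR-v567es",3
"P12","mCRPC","bulk_CTC",NA,"AR-v567es",6.27
"P13","mCRPC","bulk_CTC",NA,"AR-v567es",7.5
"P14","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P15","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P16","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P17","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P18","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P19","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P20","mCRPC","bulk_CTC",NA,"AR-v567es",8
"P21","mCRPC","bulk_CTC",NA,"AR-v567es",8.4
"P22","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P23","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P24","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P25","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P26","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P27","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P28","mCRPC","bulk_CTC",NA,"AR-v567es",0
"P29","mCRPC","bulk_CTC",NA,"AR-v567es",0
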