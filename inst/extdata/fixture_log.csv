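event_id,timestamp,participant_id,smiles,parent_event_id,score
e01,2021-03-01T09:00:00,A,C,,50
e02,2021-03-01T09:00:20,A,CC,e01,100
e03,2021-03-01T09:00:40,A,CCC,e02,150
e04,2021-03-01T09:01:10,A,CCO,e03,120
e05,2021-03-01T09:01:40,B,C,,50
e06,2021-03-01T09:02:10,B,CN,e05,80
e07,2021-03-01T09:02:40,B,CCN,e06,110
e08,2021-03-01T09:03:20,A,CCCC,e03,180
e09,2021-03-01T09:03:50,C,C1CCCCC1,,300
e10,2021-03-01T09:04:20,C,c1ccccc1,e09,600
e11,2021-03-01T09:05:00,B,CCCN,e07,140
e12,2021-03-01T09:05:40,A,Cc1ccccc1C,e10,700
e13,2021-03-01T09:06:00,A,CCc1ccccc1,e12,750
e14,2021-03-01T09:06:30,B,OCC,e11,120
e15,2021-03-01T09:07:00,C,c1ccncc1,e10,400
e16,2021-03-01T09:07:30,C,Cc1ccncc1,e15,450
e17,2021-03-01T09:08:00,B,CO,,60
e18,2021-03-01T09:08:20,B,COC,e17,90
e19,2021-03-01T09:08:50,C,CCc1ccncc1,e16,500
e20,2021-03-01T09:09:20,C,Cc1ccc(C)cc1,e16,800
e21,2021-03-01T09:10:00,A,Cc1ccccc1O,e13,850
e22,2021-03-01T09:10:40,B,CCO,e18,120
e23,2021-03-01T09:11:20,C,Cc1ccc(O)cc1,e20,900
e24,2021-03-01T09:11:40,C,Cc1ccc(N)cc1,e23,870
e25,2021-03-01T09:12:10,A,c1ccc2ccccc2c1,,200
e26,2021-03-01T09:12:40,B,c1ccsc1,,150
e27,2021-03-01T09:13:20,A,Cc1ccccc1,e21,1000
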