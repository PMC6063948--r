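trip_id,arrival_time,departure_time,stop_id,stop_sequence
L1,08:00:00,08:02:00,A,1
L1,08:10:00,08:12:00,B,2
L1,08:20:00,08:22:00,C,3
L1,08:31:00,08:33:00,D,4
L2,09:00:00,09:02:00,A,1
L2,09:11:00,09:13:00,B,2
L2,09:21:00,09:23:00,C,3
L2,09:34:00,09:36:00,D,4
X1,08:05:00,08:06:00,A,1
X1,08:17:00,08:18:00,D,2
X1,08:29:00,08:30:00,F,3
L3,10:00:00,10:01:00,D,1
L3,10:09:00,10:10:00,E,2
L3,10:19:00,10:20:00,F,3
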