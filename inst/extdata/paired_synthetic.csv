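id,sex,reference_hb,device_hb
SYN001,male,14.6,14.4
SYN002,male,11.1,11.7
SYN003,male,13.8,14.3
SYN004,male,13.3,13.1
SYN005,male,12,12
SYN006,male,8,8.5
SYN007,male,11.9,11.4
SYN008,male,11.3,11.1
SYN009,male,13.7,13.3
SYN010,male,12.5,12.4
SYN011,male,12.6,12.4
SYN012,male,11.9,12.2
SYN013,female,11.9,11.9
SYN014,female,11.8,11.1
SYN015,female,7.2,7.2
SYN016,female,15,14.4
SYN017,female,13.5,12.7
SYN018,female,12.7,12.8
SYN019,female,10.7,9.9
SYN020,female,13.7,13.6
SYN021,female,11.6,11
SYN022,female,12,12.4
SYN023,female,9.5,9.6
SYN024,female,15.2,14.8
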