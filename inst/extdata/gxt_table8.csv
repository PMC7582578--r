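subject,stage,gxt_bpm,pwb_bpm
Subject 1,Rest,85,85
Subject 1,Stage 1,109,108
Subject 1,Stage 2,113,114
Subject 1,Stage 3,119,119
Subject 1,Stage 4,126,125
Subject 1,Stage 5,140,140
Subject 1,Stage 6,153,152
Subject 1,Stage 7,165,165
Subject 1,Stage 8,176,176
Subject 2,Rest,93,93
Subject 2,Stage 1,111,111
Subject 2,Stage 2,115,114
Subject 2,Stage 3,119,120
Subject 2,Stage 4,129,130
Subject 2,Stage 5,140,141
Subject 2,Stage 6,157,158
Subject 2,Stage 7,165,165
Subject 2,Stage 8,179,179
Subject 3,Rest,83,83
Subject 3,Stage 1,112,113
Subject 3,Stage 2,116,116
Subject 3,Stage 3,122,122
Subject 3,Stage 4,131,132
Subject 3,Stage 5,143,143
Subject 3,Stage 6,156,156
Subject 3,Stage 7,168,168
Subject 3,Stage 8,180,180
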