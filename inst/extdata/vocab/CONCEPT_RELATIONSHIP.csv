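"concept_id_1","concept_id_2","relationship_id"
49000001,50000001,"ATC to RxNorm"
49000002,50000002,"ATC to RxNorm"
49000003,50000003,"ATC to RxNorm"
49000004,50000004,"ATC to RxNorm"
49000005,50000005,"ATC to RxNorm"
49000006,50000006,"ATC to RxNorm"
49000007,50000007,"ATC to RxNorm"
49000008,50000008,"ATC to RxNorm"
49000009,50000009,"ATC to RxNorm"
49000010,50000010,"ATC to RxNorm"
49000011,50000011,"ATC to RxNorm"
49000012,50000012,"ATC to RxNorm"
50000001,51000001,"RxNorm has ingredient"
50000002,51000002,"RxNorm has ingredient"
50000003,51000003,"RxNorm has ingredient"
50000004,51000004,"RxNorm has ingredient"
50000005,51000005,"RxNorm has ingredient"
50000006,51000006,"RxNorm has ingredient"
50000007,51000007,"RxNorm has ingredient"
50000008,51000008,"RxNorm has ingredient"
50000009,51000009,"RxNorm has ingredient"
50000010,51000010,"RxNorm has ingredient"
50000011,51000011,"RxNorm has ingredient"
50000012,51000002,"RxNorm has ingredient"
50000012,51000012,"RxNorm has ingredient"
52000001,49000001,"CIP to ATC"
52000002,49000002,"CIP to ATC"
52000003,49000003,"CIP to ATC"
52000004,49000004,"CIP to ATC"
52000005,49000005,"CIP to ATC"
52000006,49000006,"CIP to ATC"
52000007,49000007,"CIP to ATC"
52000008,49000008,"CIP to ATC"
52000009,49000012,"CIP to ATC"
52000010,49000009,"CIP to ATC"
52000011,49000010,"CIP to ATC"
52000012,49000011,"CIP to ATC"
52000013,49000001,"CIP to ATC"
52000014,49000004,"CIP to ATC"
52000015,49000002,"CIP to ATC"
52000016,49000008,"CIP to ATC"
52000017,49000005,"CIP to ATC"
52000018,49000013,"CIP to ATC"
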