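participant,cs_ms,ar_ms
1,427,478
2,434,477
3,437,486
4,437,487
5,438,483
6,436,484
7,435,482
8,431,479
9,431,481
10,431,481
11,433,481
12,436,482
13,438,485
14,438,485
15,436,486
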