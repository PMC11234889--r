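Activity type	Location	Object/Surface	Duration (Seconds)
Constant	Bedroom	Hard_Toy	15
Constant	Bedroom	Nothing	5
Constant	Bedroom	Hard_Toy	30
Repetitive	Kitchen	Clothing	12
Constant	Kitchen	Nothing	2
Constant	Kitchen	Sticky_Food	45
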