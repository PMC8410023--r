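individual_id	A1	A2	B1	B2	C1	C2
P01	A*01:01	A*02:01	B*01:01	B*03:01	C*01:01	C*01:01
P02	A*01:01:01:01	A*03:01	B*02:01	B*02:01	C*02:01	C*03:01
P03	A*02:01	A*02:01	B*01:01	B*02:01	C*01:01	C*02:01
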