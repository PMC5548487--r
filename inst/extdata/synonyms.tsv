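fluoxetine	RTHCYVBBDHJXIQ-UHFFFAOYSA-N
prozac	RTHCYVBBDHJXIQ-UHFFFAOYSA-N
fluoxetine hydrochloride	RTHCYVBBDHJXIQ-UHFFFAOYSA-N
aspirin	BSYNRYMUTXBXSQ-UHFFFAOYSA-N
acetylsalicylic acid	BSYNRYMUTXBXSQ-UHFFFAOYSA-N
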