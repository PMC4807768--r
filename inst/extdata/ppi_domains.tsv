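domain_accession	domain_name	class
PF00643	zf-B_box	ZF
PF00010	HLH	HLH
PF00096	zf-C2H2	ZF
PF00249	Myb_DNA-binding	TF
PF00319	SRF-TF	TF
PF01486	K-box	TF
PF00170	bZIP_1	TF
PF07716	bZIP_2	TF
PF00847	AP2	TF
PF03106	WRKY	TF
PF02362	B3	TF
PF00046	Homeodomain	TF
PF02183	HALZ	TF
PF00628	PHD	ZF
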