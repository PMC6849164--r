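uk	us
tumour	tumor
tumours	tumors
oedema	edema
oesophagus	esophagus
anaemia	anemia
haemorrhage	hemorrhage
haematoma	hematoma
ischaemia	ischemia
ischaemic	ischemic
caecum	cecum
colour	color
litre	liter
centre	center
visualised	visualized
characterised	characterized
mineralisation	mineralization
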