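# Synthetic example records (invented taxa and uses; for demonstration and
# tests only — not a transcription of any published ethnomedicinal review).
taxon	region	category	condition	source
Genusia alpha	Tropical Africa	Skin	wounds	demo-1
Genusia alpha	Tropical Africa	Gastro-intestinal	diarrhoea	demo-1
Genusia alpha	Indomalaya	fever	malaria	demo-2
Genusia beta	Tropical Africa	skin		demo-1
Genusia beta	Tropical Africa	Infections/Fever	malaria	demo-3
Genusia beta	Indomalaya	Pain	headache	demo-2
Genusia gamma	Neotropics	Infections/Fever	malaria	demo-4
Genusia gamma	Neotropics	Respiratory	cough	demo-4
Genusia delta	Neotropics	Skin		demo-4
Genusia delta	Neotropics	Gastro-intestinal		demo-5
Genusia epsilon	Indomalaya	Unspecific	tonic	demo-2
Genusia epsilon	Indomalaya	Musculo-Skeletal	rheumatism	demo-2
Genusia zeta	Tropical Africa	Genito-urinary/Fertility		demo-3
Genusia zeta	Tropical Africa	Infections/Fever	malaria	demo-3
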