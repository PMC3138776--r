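synonym	canonical
blood	Circulatory/Blood
circulatory	Circulatory/Blood
circulation	Circulatory/Blood
gastrointestinal	Gastro-intestinal
digestive	Gastro-intestinal
diarrhoea	Gastro-intestinal
diarrhea	Gastro-intestinal
dysentery	Gastro-intestinal
genito-urinary	Genito-urinary/Fertility
genitourinary	Genito-urinary/Fertility
fertility	Genito-urinary/Fertility
urinary	Genito-urinary/Fertility
fever	Infections/Fever
fevers	Infections/Fever
infection	Infections/Fever
infections	Infections/Fever
infections/fevers	Infections/Fever
anti-inflammatory	Inflammation
inflammations	Inflammation
musculoskeletal	Musculo-Skeletal
musculo-skeletal	Musculo-Skeletal
rheumatism	Musculo-Skeletal
nervous system	Nervous
analgesic	Pain
headache	Pain
poison	Poisons treatment
poisons	Poisons treatment
antidote	Poisons treatment
respiratory	Respiratory
cough	Respiratory
sensory	Sensory
eye	Sensory
ear	Sensory
skin	Skin
dermatological	Skin
wounds	Skin
tonic	Unspecific
panacea	Unspecific
unspecified	Unspecific
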