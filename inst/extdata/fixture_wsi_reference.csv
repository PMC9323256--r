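# SYNTHETIC fixture reference diagnoses (class sizes match the published design).
"slide_id","species","diagnosis"
"S01","canine","cystitis"
"S02","canine","cystitis"
"S03","feline","cystitis"
"S04","feline","cystitis"
"S05","feline","cystitis"
"S06","feline","cystitis"
"S07","feline","cystitis"
"S08","canine","neoplasia"
"S09","canine","neoplasia"
"S10","canine","neoplasia"
"S11","feline","neoplasia"
"S12","feline","neoplasia"
"S13","feline","neoplasia"
"S14","canine","urolithiasis"
"S15","canine","urolithiasis"
"S16","canine","urolithiasis"
"S17","canine","urolithiasis"
"S18","feline","urolithiasis"
"S19","feline","urolithiasis"
"S20","canine","normal"
"S21","canine","normal"
"S22","canine","normal"
"S23","canine","normal"
"S24","feline","normal"
"S25","feline","normal"
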