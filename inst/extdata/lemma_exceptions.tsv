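surface	lemma
vaping	vape
vaped	vape
vapes	vape
juuling	juul
juuled	juul
driving	drive
drove	drive
driven	drive
drives	drive
smoking	smoke
smoked	smoke
chasing	chase
chased	chase
squonking	squonk
buses	bus
busses	bus
gases	gas
men	man
women	woman
children	child
people	people
feet	foot
teeth	tooth
mice	mouse
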