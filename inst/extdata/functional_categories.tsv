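category	pattern
# coarse functional categories, one pattern per row; first match wins.
# iron before transport so iron-uptake transporters stay in the iron class.
phage & mobile elements	transposase
phage & mobile elements	mobile element
phage & mobile elements	integrase
phage & mobile elements	excisionase
phage & mobile elements	recombinase
phage & mobile elements	phage
phage & mobile elements	insertion sequence
phage & mobile elements	conjugal transfer
phage & mobile elements	relaxase
iron acquisition & metabolism	iron
iron acquisition & metabolism	siderophore
iron acquisition & metabolism	ferric
iron acquisition & metabolism	ferrous
iron acquisition & metabolism	ferredoxin
iron acquisition & metabolism	heme
iron acquisition & metabolism	hemin
membrane transport	abc transporter
membrane transport	transporter
membrane transport	permease
membrane transport	efflux
membrane transport	secretion
membrane transport	porin
membrane transport	symporter
membrane transport	antiporter
transcriptional regulation	transcriptional regulator
transcriptional regulation	transcriptional repressor
transcriptional regulation	transcriptional activator
transcriptional regulation	sigma factor
transcriptional regulation	transcription factor
stress response	chaperone
stress response	heat shock
stress response	cold shock
stress response	catalase
stress response	superoxide dismutase
stress response	osmotic
stress response	universal stress
DNA/RNA metabolism	helicase
DNA/RNA metabolism	primase
DNA/RNA metabolism	polymerase
DNA/RNA metabolism	topoisomerase
DNA/RNA metabolism	gyrase
DNA/RNA metabolism	nuclease
DNA/RNA metabolism	methyltransferase
DNA/RNA metabolism	restriction
DNA/RNA metabolism	ligase
DNA/RNA metabolism	single-stranded dna-binding
DNA/RNA metabolism	replication initiator
DNA/RNA metabolism	partitioning
DNA/RNA metabolism	ribosomal
DNA/RNA metabolism	trna
carbohydrate/amino-acid/protein metabolism	dehydrogenase
carbohydrate/amino-acid/protein metabolism	synthase
carbohydrate/amino-acid/protein metabolism	synthetase
carbohydrate/amino-acid/protein metabolism	protease
carbohydrate/amino-acid/protein metabolism	peptidase
carbohydrate/amino-acid/protein metabolism	aminotransferase
carbohydrate/amino-acid/protein metabolism	kinase
carbohydrate/amino-acid/protein metabolism	hydrolase
carbohydrate/amino-acid/protein metabolism	isomerase
carbohydrate/amino-acid/protein metabolism	reductase
carbohydrate/amino-acid/protein metabolism	glycosyl
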