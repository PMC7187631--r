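# Default species lexicon, version 1.
# canonical<TAB>surface_form, lowercase; '#' starts a comment line.
# 23 model organisms commonly catalogued for neuron morphology research.
# Surface forms cover common names, frequent Latin names, and plurals;
# this inventory is an approximation, extendable via an extra TSV.
Agouti	agouti
Agouti	agoutis
Agouti	dasyprocta
Blowfly	blowfly
Blowfly	blowflies
Blowfly	blow fly
Blowfly	blow flies
Blowfly	calliphora
Blowfly	calliphora vicina
Cat	cat
Cat	cats
Cat	felis catus
Cat	domestic cat
Chicken	chicken
Chicken	chickens
Chicken	chick
Chicken	chicks
Chicken	gallus gallus
Chicken	hen
Chicken	hens
Cricket	cricket
Cricket	crickets
Cricket	gryllus
Cricket	gryllus bimaculatus
Dragonfly	dragonfly
Dragonfly	dragonflies
Drosophila melanogaster	drosophila melanogaster
Drosophila melanogaster	drosophila
Drosophila melanogaster	fruit fly
Drosophila melanogaster	fruit flies
Drosophila melanogaster	fruitfly
Drosophila melanogaster	fruitflies
Elegans	elegans
Elegans	c elegans
Elegans	caenorhabditis elegans
Elephant	elephant
Elephant	elephants
Elephant	loxodonta
Elephant	elephas maximus
Frog	frog
Frog	frogs
Frog	xenopus
Frog	xenopus laevis
Frog	rana
Frog	tadpole
Frog	tadpoles
Goldfish	goldfish
Goldfish	goldfishes
Goldfish	carassius auratus
Guinea pig	guinea pig
Guinea pig	guinea pigs
Guinea pig	guinea-pig
Guinea pig	guinea-pigs
Guinea pig	cavia porcellus
Human	human
Human	humans
Human	homo sapiens
Monkey	monkey
Monkey	monkeys
Monkey	macaque
Monkey	macaques
Monkey	rhesus monkey
Monkey	rhesus monkeys
Monkey	rhesus macaque
Monkey	rhesus macaques
Monkey	macaca mulatta
Monkey	macaca
Monkey	marmoset
Monkey	marmosets
Moth	moth
Moth	moths
Moth	manduca sexta
Moth	manduca
Mouse	mouse
Mouse	mice
Mouse	mus musculus
Mouse	murine
Rabbit	rabbit
Rabbit	rabbits
Rabbit	oryctolagus cuniculus
Rat	rat
Rat	rats
Rat	rattus norvegicus
Rat	rattus
Salamander	salamander
Salamander	salamanders
Salamander	axolotl
Salamander	axolotls
Salamander	ambystoma
Sheep	sheep
Sheep	ovis aries
Sheep	lamb
Sheep	lambs
Sheep	ewe
Sheep	ewes
Spiny lobster	spiny lobster
Spiny lobster	spiny lobsters
Spiny lobster	panulirus
Spiny lobster	panulirus argus
Turtle	turtle
Turtle	turtles
Turtle	terrapin
Turtle	terrapins
Zebrafish	zebrafish
Zebrafish	zebra fish
Zebrafish	danio rerio
Zebrafish	brachydanio rerio
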