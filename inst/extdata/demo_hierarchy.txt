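# Minimal hyperonym hierarchy (hyponym hypernym), one edge per line.
# A German Shepherd is a kind of dog, a dog is a kind of animal; a hammer is
# a kind of tool, a tool is a kind of artifact; clouds are neither.
german_shepherd dog
tabby           cat
dog             canine
canine          animal
cat             feline
feline          animal
hammer          tool
umbrella        covering
tool            artifact
covering        artifact
animal          entity
artifact        entity
cloud           entity
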