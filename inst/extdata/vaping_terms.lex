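# name: vaping_terms
# version: 1.0
# 26 vaping-related gate terms. This bundled list is a reconstruction from
# terms standard in tobacco-control social-media surveillance; replace it via
# load_lexicon() to use a custom gate. Terms are stored in lemma form;
# multi-word entries match as contiguous token phrases, so hyphenated
# surface forms ("e-cig", "e-cigarettes") match after normalization.

[Vaping terms]
vape
vaper
vapor
vapour
vaporizer
e cig
ecig
e cigarette
ecigarette
e liquid
eliquid
e juice
ejuice
juul
vape pen
vape juice
box mod
e hookah
ehookah
nic salt
cloud chase
atomizer
cartomizer
clearomizer
mod
squonk
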