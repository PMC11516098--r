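# Pharmacophore typing rules for the built-in conformer-pair scorer.
# Each feature type maps to a list of SMARTS patterns; a molecule carries
# a type if any pattern matches. Edit freely; the scorer only uses the
# set of types present in each molecule.
donor:
  - "[$([#7;!H0]),$([#8;!H0])]"
acceptor:
  - "[$([#8;X1,X2]),$([#7;X1,X2]),$([nX2])]"
aromatic:
  - "[a]"
hydrophobe:
  - "[$([CX4;!$(C~[!#6;!#1])])]"
cation:
  - "[$([*+]),$([NX3H2;!$(NC=O)])]"
anion:
  - "[$([*-]),$([OX2H1]C(=O))]"
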