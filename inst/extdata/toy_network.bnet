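# toy regulatory module (synthetic example in the public rule-file dialect)
targets, factors
Ligand, Ligand
Receptor, Ligand AND NOT Inhibitor
Inhibitor, Effector
Effector, Receptor OR (Effector AND NOT Inhibitor)
TF, Effector AND NOT Ligand
Target, TF OR (Receptor AND Effector)
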