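# Built-in component registry.
# Molar masses are substance constants. Tm_K and dHfus_J_mol are
# LITERATURE PLACEHOLDER values (user-replaceable): replace with your own
# calorimetric determinations before making real phase-diagram predictions.
name,molar_mass_g_mol,Tm_K,dHfus_J_mol
EZB,409.4,436.2,42800
SVT,418.6,412.2,32800
FEN,360.83,353.4,33500
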