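# Example cross-linker / enzyme / modification definitions.
# Format: one [section] per definition, key = value lines.
# Residue sets are comma-separated one-letter codes; logicals true/false.

[linker]
name = BS3
end1_residues = K
end1_nterm = true
end2_residues = K,S,T,Y
end2_nterm = true
delta = 138.06808

[linker]
name = EDC
end1_residues = D,E
end2_residues = K
end2_nterm = true
delta = -18.010565

[enzyme]
name = gluc
residues = E
side = C

[modification]
name = carbamidomethyl
targets = C
delta = 57.02146
variable = false

[modification]
name = oxidation
targets = M
delta = 15.99491
variable = true
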