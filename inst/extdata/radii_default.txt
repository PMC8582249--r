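# Default heavy-atom radii (Angstrom), AMBER-style united radii.
# Columns: resname atom-name radius; '*' is a wildcard.
# Lookup order: exact (resname, name), then (*, name), then (*, element).
# Element fallbacks:
* C 1.70
* N 1.55
* O 1.50
* S 1.80
* P 1.80
* H 1.20
* D 1.20
* F 1.47
* CL 1.75
* BR 1.85
* I 1.98
* FE 1.30
* ZN 1.39
* MG 1.18
* MN 1.39
* SE 1.90
# Named exceptions: hydroxyl/carboxylate oxygens slightly larger
* OXT 1.50
* OH 1.50
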