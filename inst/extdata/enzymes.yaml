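# Protease cleavage specificities used for simulated digestion.
#
# Bond convention: 0-based bond i lies between residues i and i+1; a bond is
# cut when residue i is in `p1` and residue i+1 is NOT in `p1prime_blocked`.
# EC numbers are annotations only; enzyme names are the primary keys.
# Residue letters are quoted ("Y"/"N" would otherwise parse as booleans).
#
# The subtilisin P1 set is the calibration winner among the candidate
# readings of "large uncharged residues" (see calibrate_rules()).
pepsin:
  ec: "3.4.23.1"
  subrules:
    - p1: ["F", "L", "E"]
      p1prime_blocked: []
trypsin:
  ec: "3.4.21.4"
  subrules:
    - p1: ["K", "R"]
      p1prime_blocked: ["P"]
chymotrypsin:
  ec: "3.4.21.1"
  subrules:
    - p1: ["F", "Y", "W"]
      p1prime_blocked: ["P"]
subtilisin:
  ec: "3.4.21.62"
  subrules:
    - p1: ["F", "L", "I", "M", "V", "W", "Y", "A"]
      p1prime_blocked: []
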