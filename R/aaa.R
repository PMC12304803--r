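# Shared constants (file name keeps them first in collation order).

# Three-letter <-> one-letter amino acid mappings, 20 standard residues.
.aa321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa123 <- stats::setNames(names(.aa321), unname(.aa321))
.aa20 <- sort(unname(.aa321))

# Cross-link span categories.
.categories <- c("helix", "strand", "coil", "mixed")
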