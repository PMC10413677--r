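# Shared alphabet tables. IUPAC_CODES maps each IUPAC DNA code to the set of
# concrete bases it stands for; IUPAC_COMPLEMENT is the code-wise complement;
# ALN_ALPHABET appends the gap character for profile counting.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

ALN_ALPHABET <- c(names(IUPAC_CODES), "-")
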