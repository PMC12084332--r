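# Independent mass oracle: plain atomic-mass bookkeeping kept separate from
# the package's formula machinery, for cross-checking derived constants.
oracle_atomic <- c(
  C = 12.0, H = 1.00782503207, D = 2.01410177785,
  N = 14.0030740048, O = 15.9949146196, S = 31.97207100
)

oracle_mass <- function(...) {
  counts <- c(...)
  sum(oracle_atomic[names(counts)] * counts)
}

ORACLE_PROTON <- 1.007276
ORACLE_H2O <- oracle_mass(H = 2, O = 1)

# residue masses summed by hand from residue formulas
ORACLE_HEX <- oracle_mass(C = 6, H = 10, O = 5)
ORACLE_HEXNAC <- oracle_mass(C = 8, H = 13, N = 1, O = 5)
ORACLE_FUC <- oracle_mass(C = 6, H = 10, O = 4)
ORACLE_NEU5AC <- oracle_mass(C = 11, H = 17, N = 1, O = 8)
ORACLE_NEU5GC <- oracle_mass(C = 11, H = 17, N = 1, O = 9)
ORACLE_SO3 <- oracle_mass(S = 1, O = 3)
ORACLE_OAC <- oracle_mass(C = 2, H = 2, O = 1)

# ceramide 18:1;O2/18:0 = base C18H37NO2 + acid C18H36O2 - H2O
ORACLE_CER_18_1_18_0 <- oracle_mass(C = 18, H = 37, N = 1, O = 2) +
  oracle_mass(C = 18, H = 36, O = 2) - ORACLE_H2O
# GM1 18:1;O2/18:0 = Cer + 3 Hex + HexNAc + Neu5Ac (C73H131N3O31)
ORACLE_GM1_18_1_18_0 <- ORACLE_CER_18_1_18_0 + 3 * ORACLE_HEX +
  ORACLE_HEXNAC + ORACLE_NEU5AC
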