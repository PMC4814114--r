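`%||%` <- function(a, b) if (is.null(a)) b else a

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

# modified -> parent residue, three-letter PDB codes
MODRES_PARENT <- c(MSE = "MET", CSO = "CYS", SEP = "SER", TPO = "THR",
                   PTR = "TYR", MLY = "LYS", HYP = "PRO", CME = "CYS",
                   OCS = "CYS", KCX = "LYS", LLP = "LYS", PCA = "GLU")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa3to1 <- function(aa3) {
  aa3 <- toupper(aa3)
  parent <- ifelse(aa3 %in% names(MODRES_PARENT), MODRES_PARENT[aa3], aa3)
  out <- AA3TO1[parent]
  out[is.na(out)] <- "X"
  unname(out)
}
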