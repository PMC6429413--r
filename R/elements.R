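# Standard atomic weights (CODATA/IUPAC 2021 conventional values, amu).
.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762,
  S = 32.06, MG = 24.305, `NA` = 22.98977, K = 39.0983, CL = 35.45,
  CA = 40.078, FE = 55.845, ZN = 65.38, MN = 54.938, SE = 78.971,
  F = 18.998403, BR = 79.904, I = 126.90447, CU = 63.546, CO = 58.933
)

.MONATOMIC_IONS <- c("MG", "ZN", "FE", "MN", "NA", "CL", "K", "CA", "CU", "CO")

#' Mass of an element symbol
#'
#' @param element character vector of element symbols (e.g. "C", "MG").
#' @return numeric vector of standard atomic weights in amu.
#' @details Unknown symbols are an error: no silent default mass is assigned.
#' @export
elementMass <- function(element) {
  key <- toupper(element)
  m <- .ATOMIC_MASSES[key]
  if (any(is.na(m)))
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

# Infer the element from a PDB atom name when the element column is absent.
# Monatomic ions are recognised when the residue name matches the atom name
# (e.g. atom "MG" in residue "MG"); otherwise the leading letter of the
# cleaned atom name decides among the organic set H/C/N/O/P/S.
.guessElement <- function(name, resname) {
  clean <- gsub("[0-9'\"*]", "", toupper(trimws(name)))
  res <- toupper(trimws(resname))
  out <- character(length(clean))
  ion <- clean %in% .MONATOMIC_IONS & clean == res
  out[ion] <- clean[ion]
  rest <- !ion
  first <- substr(clean[rest], 1, 1)
  ok <- first %in% c("H", "C", "N", "O", "P", "S")
  if (any(!ok))
    stop("cannot infer element for atom name(s): ",
         paste(unique(name[rest][!ok]), collapse = ", "))
  out[rest] <- first
  out
}
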