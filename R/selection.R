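#' Select atoms by expression
#'
#' Resolves a small selection grammar against a [Structure-class] and returns
#' the matching atom indices in structure order. Clauses are joined with
#' `and`; each clause is a keyword followed by one or more values:
#'
#' \describe{
#'   \item{`name`}{atom names, e.g. `"name CA C O N"`}
#'   \item{`resid`}{residue numbers or ranges, e.g. `"resid 1:330 575"`}
#'   \item{`resname`}{residue names, e.g. `"resname HIS ATP"`}
#'   \item{`chain`}{chain identifiers, e.g. `"chain A"`}
#'   \item{`element`}{element symbols, e.g. `"element P O"`}
#' }
#'
#' @param structure a [Structure-class].
#' @param selector selection expression, e.g. `"name CA and chain A"`.
#' @return an [AtomIndexSet-class]; selecting nothing is an error because
#'   downstream matrix algebra is undefined on zero atoms.
#' @examples
#' s <- makeToyDimer(syntheticSpec(nResPerSubunit = 20, kDomainSize = 10))
#' length(selectAtoms(s, "name CA"))
#' @export
selectAtoms <- function(structure, selector) {
  stopifnot(is(structure, "Structure"))
  mask <- .selectionMask(structure@atoms, selector)
  idx <- which(mask)
  if (!length(idx))
    stop("selection '", selector, "' matched no atoms")
  new("AtomIndexSet", as.integer(idx), label = selector)
}

.selectionMask <- function(atoms, selector) {
  stopifnot(is.character(selector), length(selector) == 1, nzchar(trimws(selector)))
  clauses <- strsplit(selector, "\\s+and\\s+")[[1]]
  mask <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) < 2)
      stop("malformed selection clause: '", cl, "'")
    key <- tolower(tok[1])
    vals <- tok[-1]
    mask <- mask & switch(key,
      name = toupper(atoms$name) %in% toupper(vals),
      resid = atoms$resid %in% .expandRanges(vals),
      resno = atoms$resid %in% .expandRanges(vals),
      resname = toupper(atoms$resname) %in% toupper(vals),
      chain = atoms$chain %in% vals,
      element = toupper(atoms$element) %in% toupper(vals),
      stop("unknown selection keyword: '", tok[1], "'")
    )
  }
  mask
}

.expandRanges <- function(vals) {
  out <- integer()
  for (v in vals) {
    if (grepl(":", v, fixed = TRUE)) {
      ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
      if (length(ab) != 2 || any(is.na(ab)))
        stop("malformed residue range: '", v, "'")
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      i <- as.integer(v)
      if (is.na(i)) stop("malformed residue number: '", v, "'")
      out <- c(out, i)
    }
  }
  out
}
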