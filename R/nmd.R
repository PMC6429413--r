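# NMD arrow-file export/import, the plain-text format consumed by VMD's
# Normal Mode Wizard for porcupine plots.

#' Write modes as an NMD file
#'
#' One `coordinates` line anchors the arrows; each `mode` line carries an
#' index, a scale factor and the 3n vector components.
#'
#' @param path output path.
#' @param coords n x 3 anchor coordinates (\enc{Å}{Angstrom}).
#' @param modes 3n x k matrix of unit-norm mode vectors (columns).
#' @param scales length-k per-mode scale factors (e.g. `1/sqrt(lambda)` for
#'   normal modes, `sqrt(lambda)` for principal components).
#' @param atoms optional data.frame with `name`, `resid`, `chain` used for
#'   the `names`/`resids`/`chainids` lines.
#' @param title title line content.
#' @param modeIndices labels for the mode lines (default 1..k).
#' @return invisibly, the path.
#' @export
writeNmd <- function(path, coords, modes, scales, atoms = NULL,
                     title = "hingewatch modes", modeIndices = NULL) {
  coords <- as.matrix(coords)
  modes <- as.matrix(modes)
  k <- ncol(modes)
  stopifnot(nrow(modes) == 3 * nrow(coords), length(scales) == k)
  if (is.null(modeIndices)) modeIndices <- seq_len(k)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("title", title), con)
  if (!is.null(atoms)) {
    writeLines(paste("names", paste(atoms$name, collapse = " ")), con)
    writeLines(paste("resids", paste(atoms$resid, collapse = " ")), con)
    writeLines(paste("chainids", paste(atoms$chain, collapse = " ")), con)
  }
  writeLines(paste("coordinates",
                   paste(sprintf("%.9g", .flatten(coords)), collapse = " ")), con)
  for (j in seq_len(k))
    writeLines(paste("mode", modeIndices[j], sprintf("%.9g", scales[j]),
                     paste(sprintf("%.9g", modes[, j]), collapse = " ")), con)
  invisible(path)
}

#' Read an NMD file written by [writeNmd()]
#'
#' @param path input path.
#' @return list with `title`, `coords` (n x 3), `modes` (3n x k),
#'   `scales` and `modeIndices`.
#' @export
readNmd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(title = NULL, coords = NULL, modes = NULL,
              scales = numeric(), modeIndices = integer())
  mode_cols <- list()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    key <- tok[1]
    if (key == "title") out$title <- paste(tok[-1], collapse = " ")
    else if (key == "coordinates")
      out$coords <- .unflatten(as.numeric(tok[-1]))
    else if (key == "mode") {
      out$modeIndices <- c(out$modeIndices, as.integer(tok[2]))
      out$scales <- c(out$scales, as.numeric(tok[3]))
      mode_cols[[length(mode_cols) + 1]] <- as.numeric(tok[-(1:3)])
    }
  }
  if (is.null(out$coords)) stop("no coordinates line in NMD file '", path, "'")
  if (length(mode_cols)) out$modes <- do.call(cbind, mode_cols)
  out
}
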