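## PDB (fixed-column v3.3) input/output for bundle models, backed by bio3d.
## Multi-model files map to bundle frames.

#' Write a bundle model to a PDB file
#'
#' Writes fixed-column ATOM records (with TER between chains); a model with
#' multiple frames is written as MODEL/ENDMDL blocks.
#'
#' @param model a \code{bundle_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  frames <- bundle_frames(model)
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resno, resid = a$resname, elety = a$elety,
                   chain = a$chain, elesy = a$elem, chainter = TRUE)
  invisible(path)
}

#' Read a PDB file into a bundle model
#'
#' Multi-model files are returned as one \code{bundle_model} whose
#' \code{frames} hold one coordinate matrix per MODEL block (the atom table
#' carries the first frame).
#'
#' @param path PDB file path.
#' @return A \code{bundle_model}.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- grep("^(ATOM  |HETATM)", lines)
  for (ln in at) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop(sprintf("PDB parse error at line %d: record shorter than coordinate columns", ln))
    coords <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                            substr(l, 47, 54))))
    if (anyNA(coords))
      stop(sprintf("PDB parse error at line %d: malformed coordinate columns", ln))
    if (is.na(suppressWarnings(as.integer(substr(l, 23, 26)))))
      stop(sprintf("PDB parse error at line %d: malformed residue number", ln))
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- p$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  chain <- a$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(chain = chain, resno = a$resno, resname = a$resid,
                      elety = trimws(a$elety), elem = trimws(elem),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  m <- bundle_model(atoms)
  if (!is.null(dim(p$xyz)) && nrow(p$xyz) > 1) {
    m$frames <- lapply(seq_len(nrow(p$xyz)), function(i)
      matrix(p$xyz[i, ], ncol = 3, byrow = TRUE))
    m <- set_bundle_coords(m, m$frames[[1]])
  }
  m
}
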