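## Heptad-register projection and the polar-residue census at core positions.
##
## Coiled-coil sequences carry a seven-residue (abcdefg) repeat; positions
## 'a' and 'd' face the bundle core.  The census measures how often polar
## residues occupy selected register positions across a set of annotated
## coiled coils, optionally stratified by oligomer order (number of helices).

HEPTAD_LETTERS <- c("a", "b", "c", "d", "e", "f", "g")

#' Project a sequence onto a heptad register
#'
#' Letters advance cyclically a-b-c-d-e-f-g-a-...; the heptad number
#' increments at each 'a' position.
#'
#' @param sequence one-letter amino-acid string (or its length).
#' @param start_letter register letter of the first residue.
#' @param start_resnum residue number of the first residue.
#' @param start_heptad heptad number containing the first residue.
#' @return data frame with columns \code{resno}, \code{heptad},
#'   \code{letter} (and \code{residue} when a sequence was given).
#' @export
heptad_project <- function(sequence, start_letter = "a", start_resnum = 1L,
                           start_heptad = 1L) {
  if (is.character(sequence) && length(sequence) == 1 && nchar(sequence) > 1) {
    seqv <- strsplit(toupper(sequence), "")[[1]]
    n <- length(seqv)
  } else if (is.numeric(sequence)) {
    seqv <- NULL
    n <- as.integer(sequence)
  } else stop("sequence must be a string or a length")
  start_letter <- tolower(start_letter)
  k0 <- match(start_letter, HEPTAD_LETTERS)
  if (is.na(k0)) stop("start_letter must be one of a..g")
  idx <- (k0 - 1 + seq_len(n) - 1) %% 7 + 1
  letters_out <- HEPTAD_LETTERS[idx]
  ## heptad increments at each 'a' after the first residue
  increments <- c(0, as.integer(letters_out[-1] == "a"))
  heptad <- start_heptad + cumsum(increments)
  out <- data.frame(resno = seq(start_resnum, length.out = n),
                    heptad = heptad, letter = letters_out,
                    stringsAsFactors = FALSE)
  if (!is.null(seqv)) out$residue <- seqv
  out
}

#' Read coiled-coil register annotations from TSV
#'
#' Expects a header with columns \code{id}, \code{sequence}, \code{register},
#' \code{oligomer_order}, \code{orientation}. \code{register} is a string
#' over a..g (or '-' for unregistered residues) of the same length as
#' \code{sequence}.
#'
#' @param path TSV file path.
#' @return data frame of class \code{register_annotations} (one row per
#'   entry); an empty file yields an empty (zero-row) table.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(id = "character", sequence = "character",
                                         register = "character"))
  need <- c("id", "sequence", "register", "oligomer_order", "orientation")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  validate_annotations(df)
}

validate_annotations <- function(df) {
  for (r in seq_len(nrow(df))) {
    if (nchar(df$sequence[r]) != nchar(df$register[r]))
      stop(sprintf("annotation '%s': register length (%d) != sequence length (%d)",
                   df$id[r], nchar(df$register[r]), nchar(df$sequence[r])))
    regv <- strsplit(tolower(df$register[r]), "")[[1]]
    bad <- setdiff(unique(regv), c(HEPTAD_LETTERS, "-"))
    if (length(bad) > 0)
      stop(sprintf("annotation '%s': illegal register letter(s): %s",
                   df$id[r], paste(bad, collapse = ", ")))
    if (df$oligomer_order[r] < 2)
      stop(sprintf("annotation '%s': oligomer_order must be >= 2", df$id[r]))
  }
  class(df) <- c("register_annotations", class(df))
  df
}

#' Write a register annotation table to TSV
#'
#' @param annotations a \code{register_annotations} data frame.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Polar-residue frequencies at register positions
#'
#' For each stratum (all entries together, or entries grouped by oligomer
#' order), counts residues at the selected register positions and reports
#' the frequency of polar residues ("polar-any") plus a per-amino-acid
#' breakdown. Residues with register '-' are excluded; non-standard residue
#' codes (X, B, Z, ...) are excluded from numerator and denominator with a
#' counted warning.
#'
#' @param annotations a \code{register_annotations} data frame.
#' @param positions character vector of register letters to census
#'   (default c("a", "d"), the core positions).
#' @param stratify_by \code{"none"} or \code{"oligomer_order"}.
#' @param alphabet a \code{\link{polar_alphabet}}.
#' @return data frame of class \code{frequency_table} with columns
#'   \code{stratum}, \code{position}, \code{amino_acid} (one-letter code or
#'   \code{"polar-any"}), \code{count}, \code{denominator}, \code{frequency}.
#'   Rows with \code{position = "any"} aggregate over all selected positions.
#' @export
polar_frequency <- function(annotations, positions = c("a", "d"),
                            stratify_by = c("none", "oligomer_order"),
                            alphabet = polar_alphabet()) {
  stratify_by <- match.arg(stratify_by)
  if (nrow(annotations) == 0) stop("annotations are empty")
  positions <- tolower(positions)
  if (!all(positions %in% HEPTAD_LETTERS))
    stop("positions must be register letters a..g")

  seqv <- strsplit(toupper(paste(annotations$sequence, collapse = "")), "")[[1]]
  regv <- strsplit(tolower(paste(annotations$register, collapse = "")), "")[[1]]
  stratum <- if (stratify_by == "none") rep("all", length(seqv)) else
    rep(as.character(annotations$oligomer_order), nchar(annotations$sequence))

  keep <- regv %in% positions
  nonstd <- keep & !(seqv %in% AA1)
  n_nonstd <- sum(nonstd)
  if (n_nonstd > 0)
    warning(sprintf("%d non-standard residue(s) excluded from the census", n_nonstd))
  keep <- keep & !nonstd
  seqv <- seqv[keep]; regv <- regv[keep]; stratum <- stratum[keep]
  if (length(seqv) == 0) stop("no residues at the selected positions")

  rows <- list()
  add_block <- function(st, pos_label, s_sel) {
    denom <- length(s_sel)
    if (denom == 0) {
      warning(sprintf("stratum '%s' position '%s' has empty denominator; omitted",
                      st, pos_label))
      return()
    }
    aas <- sort(unique(s_sel))
    cnt <- table(factor(s_sel, levels = aas))
    rows[[length(rows) + 1]] <<- data.frame(
      stratum = st, position = pos_label,
      amino_acid = c("polar-any", aas),
      count = c(sum(s_sel %in% alphabet), as.integer(cnt)),
      denominator = denom, stringsAsFactors = FALSE)
  }
  for (st in unique(stratum)) {
    in_st <- stratum == st
    add_block(st, "any", seqv[in_st])
    for (p in positions) add_block(st, p, seqv[in_st & regv == p])
  }
  out <- do.call(rbind, rows)
  out$frequency <- out$count / out$denominator
  class(out) <- c("frequency_table", class(out))
  out
}

#' Write a frequency table to TSV
#'
#' @param table a \code{frequency_table}.
#' @param path output path.
#' @export
write_frequency <- function(table, path) {
  utils::write.table(table[, c("stratum", "position", "amino_acid",
                               "count", "denominator", "frequency")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a frequency in a frequency table
#'
#' Convenience accessor: the "polar-any" frequency (or a specific amino
#' acid's) for a stratum/position.
#'
#' @param table a \code{frequency_table}.
#' @param stratum stratum label (default "all").
#' @param position register letter or "any".
#' @param amino_acid one-letter code or "polar-any".
#' @return numeric frequency (NA if absent).
#' @export
get_frequency <- function(table, stratum = "all", position = "any",
                          amino_acid = "polar-any") {
  hit <- table$stratum == as.character(stratum) & table$position == position &
    table$amino_acid == amino_acid
  if (!any(hit)) return(NA_real_)
  table$frequency[which(hit)[1]]
}
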