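## Polarity conservation across paired alignments of two interacting
## coiled-coil proteins.  Each alignment pair (same taxa in both files) is
## projected onto the heptad register of a reference sequence; the polar /
## nonpolar state at each core (a/d) position yields a binary pattern per
## pair, summarized as a weighted path graph (a Sankey-style flow: edge
## weight = number of pairs following a given polar/nonpolar transition)
## and as conservation statistics.

#' Read a paired alignment set from two FASTA alignment files
#'
#' Sequences are matched by identifier (the first whitespace-delimited token
#' of each FASTA header); both alignments must contain the reference and the
#' same taxa. Duplicated taxa are rejected.
#'
#' @param ftsb_path,ftsl_path aligned FASTA files for the two proteins
#'   (conventionally FtsB-like first, FtsL-like second).
#' @param reference_id identifier of the reference pair (e.g. the E. coli
#'   sequences) present in both alignments.
#' @return list of class \code{paired_alignment} with elements \code{ids},
#'   \code{b} and \code{l} (named character vectors of aligned sequences)
#'   and \code{reference_id}.
#' @export
read_paired_alignment <- function(ftsb_path, ftsl_path, reference_id) {
  rd <- function(path) {
    ss <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
    if (anyDuplicated(ids))
      stop("duplicate taxon id(s) in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    x <- toupper(as.character(ss))
    names(x) <- ids
    if (length(unique(nchar(x))) > 1)
      stop("aligned sequences in ", path, " differ in length")
    x
  }
  b <- rd(ftsb_path); l <- rd(ftsl_path)
  common <- intersect(names(b), names(l))
  if (!(reference_id %in% common))
    stop("reference id '", reference_id, "' missing from one of the alignments")
  structure(list(ids = common, b = b[common], l = l[common],
                 reference_id = reference_id),
            class = "paired_alignment")
}

#' Paired alignment from in-memory vectors
#'
#' @param b,l named character vectors of aligned sequences (same names).
#' @param reference_id name of the reference pair.
#' @return A \code{paired_alignment}.
#' @export
paired_alignment <- function(b, l, reference_id) {
  common <- intersect(names(b), names(l))
  if (anyDuplicated(names(b)) || anyDuplicated(names(l)))
    stop("duplicate taxon ids")
  if (!(reference_id %in% common)) stop("reference id missing")
  structure(list(ids = common, b = toupper(b[common]), l = toupper(l[common]),
                 reference_id = reference_id),
            class = "paired_alignment")
}

#' Map alignment columns to heptad registers via reference anchors
#'
#' Anchors give the register of specific reference residues (by residue
#' number); the register is propagated by heptad cycling across the
#' reference's coiled-coil window. Columns where the reference has a gap get
#' no register. Conflicting anchors (implying different heptad phases) are
#' an error.
#'
#' @param aln a \code{paired_alignment}.
#' @param protein \code{"b"} or \code{"l"}.
#' @param anchors data frame with columns \code{resno}, \code{heptad},
#'   \code{letter}: known register assignments of reference residues.
#' @param first_resnum residue number of the first reference residue in the
#'   alignment (gaps not counted).
#' @param window integer vector of heptad numbers forming the coiled-coil
#'   window (default 1:5).
#' @return data frame with one row per alignment column carrying a reference
#'   residue inside the window: \code{column}, \code{resno}, \code{heptad},
#'   \code{letter}.
#' @export
map_register <- function(aln, protein = c("b", "l"), anchors,
                         first_resnum = 1L, window = 1:5) {
  protein <- match.arg(protein)
  refseq <- aln[[protein]][[aln$reference_id]]
  refv <- strsplit(refseq, "")[[1]]
  is_res <- !(refv %in% c("-", "."))
  resno <- rep(NA_integer_, length(refv))
  resno[is_res] <- seq(first_resnum, length.out = sum(is_res))

  ## each anchor implies a phase: (letter index - resno) mod 7 and an
  ## absolute heptad anchoring; all anchors must agree
  phase <- heptad0 <- NULL
  for (r in seq_len(nrow(anchors))) {
    li <- match(tolower(anchors$letter[r]), HEPTAD_LETTERS)
    if (is.na(li)) stop("anchor letter must be a..g")
    ph <- (li - 1 - anchors$resno[r]) %% 7
    ## residue number of the 'a' position of this anchor's heptad
    a_resno <- anchors$resno[r] - (li - 1)
    if (is.null(phase)) {
      phase <- ph
      anchor_a <- a_resno
      anchor_h <- anchors$heptad[r]
    } else {
      if (ph != phase ||
          (a_resno - anchor_a) %% 7 != 0 ||
          anchors$heptad[r] != anchor_h + (a_resno - anchor_a) %/% 7)
        stop(sprintf("anchor conflict at residue %d: inconsistent heptad phase",
                     anchors$resno[r]))
    }
  }
  letter_idx <- (resno + phase) %% 7 + 1
  heptad <- anchor_h + floor((resno - anchor_a) / 7)
  keep <- is_res & heptad %in% window
  data.frame(column = which(keep), resno = resno[keep],
             heptad = heptad[keep], letter = HEPTAD_LETTERS[letter_idx[keep]],
             stringsAsFactors = FALSE)
}

#' Binary polar/nonpolar pattern matrix at core positions
#'
#' One row per pair, one column per a/d core position (first protein's block
#' then the second's, each ordered by heptad). Entries are \code{"P"}
#' (polar), \code{"N"} (nonpolar) or \code{NA} (gap or non-standard residue).
#'
#' @param aln a \code{paired_alignment}.
#' @param map_b,map_l register maps from \code{\link{map_register}} for the
#'   two proteins.
#' @param positions core register letters (default a and d).
#' @param alphabet a \code{\link{polar_alphabet}}.
#' @return character matrix of class \code{binary_patterns} with column
#'   metadata in \code{attr(, "columns")} (protein, resno, heptad, letter).
#' @export
binary_patterns <- function(aln, map_b, map_l, positions = c("a", "d"),
                            alphabet = polar_alphabet()) {
  sel_b <- map_b[map_b$letter %in% positions, ]
  sel_l <- map_l[map_l$letter %in% positions, ]
  cols <- rbind(cbind(protein = "b", sel_b), cbind(protein = "l", sel_l))
  n <- length(aln$ids)
  state_block <- function(seqs, sel) {
    m <- do.call(rbind, strsplit(unname(seqs), ""))
    block <- m[, sel$column, drop = FALSE]
    out <- matrix(NA_character_, nrow(block), ncol(block))
    out[block %in% alphabet] <- "P"
    out[block %in% setdiff(AA1, alphabet)] <- "N"
    out
  }
  mat <- cbind(state_block(aln$b, sel_b), state_block(aln$l, sel_l))
  rownames(mat) <- aln$ids
  colnames(mat) <- paste0(cols$protein, cols$heptad, cols$letter)
  attr(mat, "columns") <- cols
  class(mat) <- c("binary_patterns", class(mat))
  mat
}

#' Weighted path graph of binary patterns
#'
#' Edges connect states of adjacent columns; the weight of edge
#' (column i, state s) -> (column i+1, state t) is the number of pairs in
#' state s at column i and t at column i+1 (rows missing either state are
#' skipped for that transition). Node weights count states per column.
#'
#' @param matrix a \code{binary_patterns} matrix.
#' @return list of class \code{path_graph} with data frames \code{nodes}
#'   (column, state, count) and \code{edges} (from_column, from_state,
#'   to_column, to_state, weight).
#' @export
path_graph <- function(matrix) {
  if (nrow(matrix) < 1) stop("need at least one pattern row")
  nc <- ncol(matrix)
  cn <- colnames(matrix)
  nodes <- do.call(rbind, lapply(seq_len(nc), function(j) {
    tt <- table(factor(matrix[, j], levels = c("P", "N")))
    data.frame(column = cn[j], state = names(tt), count = as.integer(tt),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(seq_len(nc - 1), function(j) {
    ok <- !is.na(matrix[, j]) & !is.na(matrix[, j + 1])
    tt <- table(factor(matrix[ok, j], levels = c("P", "N")),
                factor(matrix[ok, j + 1], levels = c("P", "N")))
    df <- as.data.frame(tt, stringsAsFactors = FALSE)
    names(df) <- c("from_state", "to_state", "weight")
    df$from_column <- cn[j]; df$to_column <- cn[j + 1]
    df[df$weight > 0, c("from_column", "from_state", "to_column", "to_state", "weight")]
  }))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "path_graph")
}

#' Write a path graph's edge list as TSV (for Sankey-style plotting)
#'
#' @param graph a \code{path_graph}.
#' @param path output TSV path.
#' @export
write_path_graph <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Conservation summary of a binary pattern matrix
#'
#' Reports (i) the polar fraction per core column; (ii) the fraction of
#' pairs with at least one polar residue among the second protein's (FtsL
#' block) a/d positions of heptads 1-2; (iii) the joint distribution of
#' (number of polar core residues in protein b, in protein l); (iv) the
#' fraction of pairs with total polar core count >= k. For each statistic,
#' rows with any missing entry in the relevant window are dropped from the
#' denominator.
#'
#' @param matrix a \code{binary_patterns} matrix.
#' @return list of class \code{conservation_summary}: \code{per_column}
#'   (data frame), \code{frac_polar_l_heptads12}, \code{class_freq} (data
#'   frame over (n_polar_b, n_polar_l)), \code{frac_at_least} (named vector
#'   over k), \code{n_pairs}.
#' @export
conservation_summary <- function(matrix) {
  if (nrow(matrix) == 0) stop("empty pattern matrix")
  cols <- attr(matrix, "columns")
  per_column <- data.frame(
    column = colnames(matrix),
    polar_fraction = vapply(seq_len(ncol(matrix)), function(j) {
      x <- matrix[, j]; mean(x[!is.na(x)] == "P")
    }, numeric(1)),
    stringsAsFactors = FALSE)

  l12 <- which(cols$protein == "l" & cols$heptad %in% 1:2)
  sub <- matrix[, l12, drop = FALSE]
  full <- rowSums(is.na(sub)) == 0
  frac_l12 <- if (any(full)) mean(rowSums(sub[full, , drop = FALSE] == "P") >= 1) else NA_real_

  bcols <- which(cols$protein == "b"); lcols <- which(cols$protein == "l")
  full_all <- rowSums(is.na(matrix)) == 0
  nb <- rowSums(matrix[full_all, bcols, drop = FALSE] == "P")
  nl <- rowSums(matrix[full_all, lcols, drop = FALSE] == "P")
  cls <- table(nb, nl)
  class_freq <- as.data.frame(cls, stringsAsFactors = FALSE)
  names(class_freq) <- c("n_polar_b", "n_polar_l", "count")
  class_freq$n_polar_b <- as.integer(class_freq$n_polar_b)
  class_freq$n_polar_l <- as.integer(class_freq$n_polar_l)
  class_freq <- class_freq[class_freq$count > 0, ]
  class_freq$frequency <- class_freq$count / sum(class_freq$count)
  rownames(class_freq) <- NULL

  total <- nb + nl
  kmax <- max(total, 0)
  frac_at_least <- vapply(seq_len(max(kmax, 1)), function(k) mean(total >= k),
                          numeric(1))
  names(frac_at_least) <- seq_along(frac_at_least)

  structure(list(per_column = per_column,
                 frac_polar_l_heptads12 = frac_l12,
                 class_freq = class_freq,
                 frac_at_least = frac_at_least,
                 n_pairs = nrow(matrix),
                 n_complete = sum(full_all)),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("Conservation summary over %d pairs (%d with complete core):\n",
              x$n_pairs, x$n_complete))
  cat(sprintf("  >=1 polar at FtsL-block a/d of heptads 1-2: %.1f%%\n",
              100 * x$frac_polar_l_heptads12))
  top <- x$class_freq[which.max(x$class_freq$frequency), ]
  cat(sprintf("  most common (b,l) polar-count class: (%d,%d) at %.1f%%\n",
              top$n_polar_b, top$n_polar_l, 100 * top$frequency))
  if ("5" %in% names(x$frac_at_least))
    cat(sprintf("  >=5 polar core residues: %.1f%%\n", 100 * x$frac_at_least[["5"]]))
  invisible(x)
}
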