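## Rigid-body grafting of a loop fragment onto a bundle at anchor residues.
## The fragment carries n_flank helical residues on each side of its core;
## the flanks are least-squares superposed (over CA atoms) onto the matching
## anchor residues of the model, and the core replaces (or is inserted at)
## the target site.

#' Graft a fragment into a bundle model
#'
#' The fragment's flanking residues (\code{n_flank} on each side of its core)
#' are superposed onto the model's anchor residues around the target site;
#' the transformed core residues then replace the site. A site with
#' \code{end < start} denotes a pure insertion between residues \code{end}
#' and \code{start} (no residues removed).
#'
#' @param model a \code{bundle_model}.
#' @param fragment atom data frame (or \code{bundle_model}) of the fragment:
#'   \code{n_flank} + core + \code{n_flank} consecutive residues.
#' @param target_site list with \code{chain}, \code{start}, \code{end}:
#'   the residue range of \code{chain} replaced by the fragment core.
#' @param n_flank number of flanking helical residues on each side used as
#'   superposition anchors.
#' @param max_flank_rmsd grafts whose optimal flank-CA RMSD exceeds this
#'   (Angstrom) are rejected with an error.
#' @return A \code{bundle_model} with the graft applied, residues of the
#'   grafted chain renumbered consecutively; the flank RMSD is attached as
#'   attribute \code{"flank_rmsd"}.
#' @export
graft_fragment <- function(model, fragment, target_site, n_flank = 4,
                           max_flank_rmsd = 1.5) {
  if (inherits(fragment, "bundle_model")) fragment <- fragment$atoms
  ch <- target_site$chain
  start <- target_site$start; end <- target_site$end
  a <- model$atoms
  chain_res <- sort(unique(a$resno[a$chain == ch]))
  if (length(chain_res) == 0) stop("target chain not found: ", ch)

  pre_anchor <- chain_res[chain_res < start]
  post_anchor <- chain_res[chain_res > end]
  if (length(pre_anchor) < n_flank || length(post_anchor) < n_flank)
    stop(sprintf("need %d anchor residues on each side of the site", n_flank))
  pre_anchor <- utils::tail(pre_anchor, n_flank)
  post_anchor <- utils::head(post_anchor, n_flank)

  frag_res <- sort(unique(fragment$resno))
  n_core <- length(frag_res) - 2 * n_flank
  if (n_core < 0)
    stop(sprintf("fragment has %d residues, fewer than 2 * n_flank = %d",
                 length(frag_res), 2 * n_flank))
  frag_pre <- frag_res[seq_len(n_flank)]
  frag_post <- frag_res[(length(frag_res) - n_flank + 1):length(frag_res)]
  frag_core <- setdiff(frag_res, c(frag_pre, frag_post))

  ca_of <- function(df, chain, res) {
    out <- t(vapply(res, function(r) {
      row <- if (is.null(chain)) df[df$resno == r & df$elety == "CA", ]
             else df[df$chain == chain & df$resno == r & df$elety == "CA", ]
      if (nrow(row) == 0) stop("missing CA for residue ", r)
      c(row$x[1], row$y[1], row$z[1])
    }, numeric(3)))
    out
  }
  anchor_ca <- rbind(ca_of(a, ch, pre_anchor), ca_of(a, ch, post_anchor))
  flank_ca <- rbind(ca_of(fragment, NULL, frag_pre), ca_of(fragment, NULL, frag_post))
  fit <- kabsch_superpose(flank_ca, anchor_ca)
  if (fit$rmsd > max_flank_rmsd)
    stop(sprintf("graft rejected: flank RMSD %.3f A exceeds %.2f A (anchors incompatible)",
                 fit$rmsd, max_flank_rmsd))

  core <- fragment[fragment$resno %in% frag_core, , drop = FALSE]
  if (nrow(core) > 0) {
    xyz <- fit$transform(as.matrix(core[, c("x", "y", "z")]))
    core$x <- xyz[, 1]; core$y <- xyz[, 2]; core$z <- xyz[, 3]
    core$chain <- ch
    ## temporary residue numbers that cannot collide with the model's
    core$resno <- max(a$resno) + 1000L + match(core$resno, frag_core)
  }

  target_before <- a[a$chain == ch & a$resno < start, , drop = FALSE]
  after <- a[a$chain == ch & a$resno > end, , drop = FALSE]
  others <- a[a$chain != ch, , drop = FALSE]
  new_chain <- rbind(target_before, core, after)

  ## renumber the grafted chain consecutively from its first residue number
  res_seq <- unique(new_chain$resno)
  first <- min(a$resno[a$chain == ch])
  remap <- stats::setNames(seq(first, length.out = length(res_seq)),
                           as.character(res_seq))
  ord <- order(match(new_chain$resno, res_seq))
  new_chain <- new_chain[ord, , drop = FALSE]
  new_chain$resno <- unname(remap[as.character(new_chain$resno)])

  atoms <- rbind(new_chain, others)
  rownames(atoms) <- NULL
  out <- bundle_model(atoms, specs = model$specs, symmetry_ops = model$symmetry_ops)
  attr(out, "flank_rmsd") <- fit$rmsd
  out
}
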