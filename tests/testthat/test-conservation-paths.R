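# Register mapping over paired alignments, binary polarity patterns, the
# weighted path graph and the conservation summaries.

# anchors used throughout: FtsB-block residues numbered from 29 (so 39 = 2d,
# 43 = 3a), FtsL-block residues from 60 (67 = 2a, 74 = 3a)
anchors_b <- data.frame(resno = c(39, 43), heptad = c(2, 3), letter = c("d", "a"))
anchors_l <- data.frame(resno = c(67, 74), heptad = c(2, 3), letter = c("a", "a"))

ec_pair <- function(extra = NULL) {
  b <- c(Ec_ref = coilbundle:::REF_FTSB)
  l <- c(Ec_ref = coilbundle:::REF_FTSL)
  if (!is.null(extra)) {
    b <- c(b, vapply(extra, `[[`, character(1), "b"))
    l <- c(l, vapply(extra, `[[`, character(1), "l"))
  }
  paired_alignment(b, l, "Ec_ref")
}

test_that("an ungapped reference maps to a pure heptad cycle", {
  aln <- ec_pair()
  mp <- map_register(aln, "b", anchors_b, first_resnum = 29, window = 1:5)
  expect_equal(nrow(mp), 35)
  expect_equal(mp$letter, rep(c("a", "b", "c", "d", "e", "f", "g"), 5))
  expect_equal(mp$heptad, rep(1:5, each = 7))
  expect_equal(mp$column, 1:35)
})

test_that("gap columns in the reference do not shift register assignments", {
  b <- coilbundle:::REF_FTSB
  gapped <- paste0(substr(b, 1, 10), "--", substr(b, 11, 35))
  aln <- paired_alignment(c(Ec_ref = gapped),
                          c(Ec_ref = paste0(coilbundle:::REF_FTSL, "--")),
                          "Ec_ref")
  mp0 <- map_register(ec_pair(), "b", anchors_b, first_resnum = 29)
  mp1 <- map_register(aln, "b", anchors_b, first_resnum = 29)
  expect_equal(mp1$resno, mp0$resno)
  expect_equal(mp1$letter, mp0$letter)
  # columns after the gap shift by the gap width
  expect_equal(mp1$column[mp1$resno == 43], mp0$column[mp0$resno == 43] + 2)
})

test_that("inconsistent anchors are rejected", {
  bad <- data.frame(resno = c(39, 43), heptad = c(2, 3), letter = c("d", "b"))
  expect_error(map_register(ec_pair(), "b", bad, first_resnum = 29),
               "anchor conflict")
})

test_that("the E. coli pair is polar exactly at the six conserved core positions", {
  aln <- ec_pair()
  mb <- map_register(aln, "b", anchors_b, first_resnum = 29)
  ml <- map_register(aln, "l", anchors_l, first_resnum = 60)
  pat <- binary_patterns(aln, mb, ml)
  expect_equal(ncol(pat), 20)
  polar_cols <- colnames(pat)[pat["Ec_ref", ] == "P"]
  expect_setequal(polar_cols, c("b2d", "b3a", "b4a", "l2a", "l3a", "l5a"))
})

test_that("all-nonpolar and gapped pairs produce the expected pattern rows", {
  leu <- strrep("L", 35)
  gap_b <- paste0(substr(coilbundle:::REF_FTSB, 1, 14), "-",
                  substr(coilbundle:::REF_FTSB, 16, 35))  # column 15 = 3a
  aln <- ec_pair(list(leu = list(b = leu, l = leu),
                      gapped = list(b = gap_b, l = coilbundle:::REF_FTSL)))
  mb <- map_register(aln, "b", anchors_b, first_resnum = 29)
  ml <- map_register(aln, "l", anchors_l, first_resnum = 60)
  pat <- binary_patterns(aln, mb, ml)
  expect_true(all(pat["leu", ] == "N"))
  expect_equal(sum(is.na(pat["gapped", ])), 1)
  expect_true(is.na(pat["gapped", "b3a"]))
})

test_that("path graph edge weights tally binary transitions exactly", {
  rows <- c(rep("PP", 4), rep("PN", 3), rep("NP", 2), "NN")
  m <- do.call(rbind, strsplit(rows, ""))
  m[m == "P"] <- "P"; m[m == "N"] <- "N"
  rownames(m) <- paste0("r", seq_len(nrow(m)))
  colnames(m) <- c("b1a", "b1d")
  attr(m, "columns") <- data.frame(protein = "b", column = 1:2, resno = 1:2,
                                   heptad = 1, letter = c("a", "d"))
  class(m) <- c("binary_patterns", class(m))
  g <- path_graph(m)
  w <- function(fs, ts) g$edges$weight[g$edges$from_state == fs & g$edges$to_state == ts]
  expect_equal(w("P", "P"), 4)
  expect_equal(w("P", "N"), 3)
  expect_equal(w("N", "P"), 2)
  expect_equal(w("N", "N"), 1)
})

test_that("flow is conserved at interior columns and a uniform set is one path", {
  gen <- gen_paired_alignment(n_pairs = 200, gap_rate = 0.02, seed = 13)
  mb <- map_register(gen$aln, "b", anchors_b, first_resnum = 29)
  ml <- map_register(gen$aln, "l", anchors_l, first_resnum = 60)
  pat <- binary_patterns(gen$aln, mb, ml)
  g <- path_graph(pat)
  cn <- colnames(pat)
  for (j in 2:(length(cn) - 1)) {
    ok_in <- !is.na(pat[, j - 1]) & !is.na(pat[, j])
    ok_out <- !is.na(pat[, j]) & !is.na(pat[, j + 1])
    inflow <- sum(g$edges$weight[g$edges$to_column == cn[j]])
    outflow <- sum(g$edges$weight[g$edges$from_column == cn[j]])
    expect_equal(inflow, sum(ok_in))
    expect_equal(outflow, sum(ok_out))
  }

  allP <- matrix("P", 10, 3, dimnames = list(paste0("r", 1:10), c("b1a", "b1d", "b2a")))
  attr(allP, "columns") <- data.frame(protein = "b", column = 1:3, resno = 1:3,
                                      heptad = c(1, 1, 2), letter = c("a", "d", "a"))
  class(allP) <- c("binary_patterns", class(allP))
  gP <- path_graph(allP)
  expect_true(all(gP$edges$weight == 10))
  expect_equal(nrow(gP$edges), 2)
})

test_that("conservation summaries handle degenerate matrices", {
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- c(paste0("b", rep(1:5, each = 2), c("a", "d")),
                     paste0("l", rep(1:5, each = 2), c("a", "d")))
    rownames(m) <- paste0("r", seq_along(rows))
    attr(m, "columns") <- data.frame(
      protein = rep(c("b", "l"), each = 10), column = 1:20, resno = 1:20,
      heptad = rep(rep(1:5, each = 2), 2), letter = rep(c("a", "d"), 10))
    class(m) <- c("binary_patterns", class(m))
    m
  }
  one <- mk(list(c("N", "N", "N", "P", "P", "N", "P", "N", "N", "N",
                   "N", "N", "P", "N", "P", "N", "N", "N", "P", "N")))
  s <- conservation_summary(one)
  expect_equal(s$class_freq$frequency[s$class_freq$n_polar_b == 3 &
                                        s$class_freq$n_polar_l == 3], 1)
  expect_equal(unname(s$frac_at_least[["5"]]), 1)

  none <- mk(rep(list(rep("N", 20)), 5))
  s0 <- conservation_summary(none)
  expect_true(all(s0$per_column$polar_fraction == 0))
  expect_equal(s0$frac_polar_l_heptads12, 0)
  expect_equal(s0$class_freq$frequency[s0$class_freq$n_polar_b == 0 &
                                         s0$class_freq$n_polar_l == 0], 1)
  expect_error(conservation_summary(one[0, , drop = FALSE]), "empty")
})

test_that("summaries recover the generator's calibrated statistics within binomial CIs", {
  gen <- gen_paired_alignment(n_pairs = 2900, gap_rate = 0.01, seed = 4)
  mb <- map_register(gen$aln, "b", anchors_b, first_resnum = 29)
  ml <- map_register(gen$aln, "l", anchors_l, first_resnum = 60)
  pat <- binary_patterns(gen$aln, mb, ml)
  s <- conservation_summary(pat)
  tr <- gen$truth
  # each recovered statistic must sit inside the exact binomial 95% CI
  # around its estimate (the generating value is the truth)
  sub <- pat[, attr(pat, "columns")$protein == "l" &
               attr(pat, "columns")$heptad %in% 1:2, drop = FALSE]
  n12 <- sum(rowSums(is.na(sub)) == 0)
  ci <- binom_ci(round(s$frac_polar_l_heptads12 * n12), n12)
  expect_gte(tr$frac_polar_l_heptads12, ci[1])
  expect_lte(tr$frac_polar_l_heptads12, ci[2])

  c33 <- s$class_freq$frequency[s$class_freq$n_polar_b == 3 &
                                  s$class_freq$n_polar_l == 3]
  ci <- binom_ci(round(c33 * s$n_complete), s$n_complete)
  expect_gte(tr$class_33, ci[1])
  expect_lte(tr$class_33, ci[2])

  ci <- binom_ci(round(unname(s$frac_at_least[["5"]]) * s$n_complete), s$n_complete)
  expect_gte(tr$frac_ge5, ci[1])
  expect_lte(tr$frac_ge5, ci[2])
})

test_that("column polar fractions ignore row order", {
  gen <- gen_paired_alignment(n_pairs = 80, seed = 9)
  mb <- map_register(gen$aln, "b", anchors_b, first_resnum = 29)
  ml <- map_register(gen$aln, "l", anchors_l, first_resnum = 60)
  pat <- binary_patterns(gen$aln, mb, ml)
  s1 <- conservation_summary(pat)
  perm <- pat[sample(nrow(pat)), , drop = FALSE]
  attr(perm, "columns") <- attr(pat, "columns")
  class(perm) <- class(pat)
  s2 <- conservation_summary(perm)
  expect_equal(s2$per_column$polar_fraction, s1$per_column$polar_fraction)
})

test_that("alignment FASTA IO round-trips through the reader", {
  dir <- tempfile()
  gen <- gen_paired_alignment(n_pairs = 25, seed = 2, dir = dir)
  aln <- read_paired_alignment(file.path(dir, "ftsb.aln.fasta"),
                               file.path(dir, "ftsl.aln.fasta"), "Ec_ref")
  expect_equal(sort(aln$ids), sort(gen$aln$ids))
  expect_equal(unname(aln$b["Ec_ref"]), coilbundle:::REF_FTSB)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$n_pairs, 25)
})
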