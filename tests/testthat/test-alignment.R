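test_that("pair classification matches the hand-written truth table", {
  # exhaustive 4x4 base table
  truth <- list(
    AA = "MATCH", AC = "TV", AG = "RR", AT = "TV",
    CA = "TV", CC = "MATCH", CG = "TV", CT = "YY",
    GA = "RR", GC = "TV", GG = "MATCH", GT = "TV",
    TA = "TV", TC = "YY", TG = "TV", TT = "MATCH")
  wobbles <- c("GA", "TC")
  for (g in c("A", "C", "G", "T")) {
    for (s in c("A", "C", "G", "T")) {
      got <- classify_pair(g, s)
      expect_equal(got$class, truth[[paste0(g, s)]],
                   label = paste0("class(", g, ",", s, ")"))
      expect_equal(got$wobble, paste0(g, s) %in% wobbles,
                   label = paste0("wobble(", g, ",", s, ")"))
    }
  }
  expect_equal(classify_pair("A", "-")$class, "RNA_BULGE")
  expect_equal(classify_pair("-", "A")$class, "DNA_BULGE")
  expect_error(classify_pair("-", "-"), "two gaps")
})

test_that("identity, substitution and bulge alignments score as expected", {
  aln <- align_guide_to_site("GATTACAGATTACAGATTAC",
                             "GATTACAGATTACAGATTAC")
  expect_equal(aln$counts$mismatches, 0L)
  expect_equal(aln$counts$rna_bulges + aln$counts$dna_bulges, 0L)
  expect_equal(aln$score, 20)

  aln <- align_guide_to_site("ACGT", "AGGT")
  expect_equal(aln$counts$mismatches, 1L)
  expect_equal(aln$counts$rna_bulges + aln$counts$dna_bulges, 0L)
  expect_equal(aln$score, 2)
  expect_equal(aln$score, brute_force_align_score("ACGT", "AGGT"))

  # site one base shorter: a gap appears in the site row (RNA bulge)
  aln <- align_guide_to_site("ACGTA", "ACTA")
  expect_equal(aln$counts$rna_bulges, 1L)
  expect_equal(aln$score, 4 * 1 + (-2))
  expect_equal(aln$score, brute_force_align_score("ACGTA", "ACTA"))

  expect_error(align_guide_to_site("", "ACGT"), "non-empty")
  expect_error(align_guide_to_site("ACGT", "ACXT"), "non-ACGT")
})

test_that("DP score equals exhaustive enumeration for short pairs", {
  set.seed(20)
  # dense coverage at short lengths, sampled pairs up to length 8
  for (rep in 1:40) {
    la <- sample(1:5, 1)
    lb <- sample(1:5, 1)
    a <- random_seq(la)
    b <- random_seq(lb)
    expect_equal(align_guide_to_site(a, b)$score,
                 brute_force_align_score(a, b),
                 label = paste("pair", a, b))
  }
  for (rep in 1:6) {
    la <- sample(6:8, 1)
    lb <- sample(6:8, 1)
    a <- random_seq(la)
    b <- random_seq(lb)
    expect_equal(align_guide_to_site(a, b)$score,
                 brute_force_align_score(a, b),
                 label = paste("pair", a, b))
  }
  # non-default scoring triple
  for (rep in 1:10) {
    a <- random_seq(4)
    b <- random_seq(5)
    expect_equal(
      align_guide_to_site(a, b, c(match = 2, mismatch = -3, gap = -1))$score,
      brute_force_align_score(a, b, 2, -3, -1))
  }
})

test_that("column counts conserve and swap symmetrically", {
  set.seed(21)
  for (rep in 1:50) {
    a <- random_seq(sample(8:20, 1))
    b <- random_seq(sample(8:20, 1))
    aln <- align_guide_to_site(a, b)
    cts <- aln$counts
    n_match <- sum(aln$columns$class == "MATCH")
    expect_equal(n_match + cts$mismatches + cts$rna_bulges +
                   cts$dna_bulges, nrow(aln$columns))
    expect_equal(cts$mismatches, cts$tv_total + cts$rr_total +
                   cts$yy_total)
    expect_lte(cts$mismatches_17_20, cts$mismatches)
    # swapping the sequences swaps the bulge classes, score unchanged
    rev <- align_guide_to_site(b, a)
    expect_equal(rev$score, aln$score)
    expect_equal(rev$counts$rna_bulges, cts$dna_bulges)
    expect_equal(rev$counts$dna_bulges, cts$rna_bulges)
  }
})

test_that("an extra substitution never raises the alignment score", {
  set.seed(22)
  for (rep in 1:30) {
    g <- random_seq(20)
    aln0 <- align_guide_to_site(g, g)
    ch <- strsplit(g, "")[[1]]
    p <- sample(20, 1)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    aln1 <- align_guide_to_site(g, paste(ch, collapse = ""))
    expect_lte(aln1$score, aln0$score)
  }
})

test_that("positional mismatch window counts use PAM-distal numbering", {
  g <- "GATTACAGATTACAGATTAC"
  ch <- strsplit(g, "")[[1]]
  ch[18] <- setdiff(c("A", "C", "G", "T"), ch[18])[1]
  aln <- align_guide_to_site(g, paste(ch, collapse = ""))
  expect_equal(positional_mismatches(aln, c(17, 20)), 1L)
  expect_equal(aln$counts$mismatches_17_20, 1L)

  ch <- strsplit(g, "")[[1]]
  ch[3] <- setdiff(c("A", "C", "G", "T"), ch[3])[1]
  aln <- align_guide_to_site(g, paste(ch, collapse = ""))
  expect_equal(positional_mismatches(aln, c(17, 20)), 0L)
  expect_equal(positional_mismatches(aln, c(1, 4)), 1L)
  expect_error(positional_mismatches(aln, c(17, 25)), "outside")

  # a 17-nt guide: the seed window is its 4 PAM-proximal positions
  g17 <- substr(g, 1, 17)
  ch <- strsplit(g17, "")[[1]]
  ch[16] <- setdiff(c("A", "C", "G", "T"), ch[16])[1]
  aln <- align_guide_to_site(g17, paste(ch, collapse = ""))
  expect_equal(aln$counts$mismatches_17_20, 1L)

  # window count bounded by total mismatches over random alignments
  set.seed(23)
  for (rep in 1:200) {
    a <- random_seq(20)
    b <- random_seq(20)
    aln <- align_guide_to_site(a, b)
    w <- positional_mismatches(aln, c(17, 20))
    expect_lte(w, aln$counts$mismatches)
  }
})
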