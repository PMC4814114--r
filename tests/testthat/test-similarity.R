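# One-helix alignment entries with full control over the TM1 sequence; the
# other six helices carry a shared dummy segment.
mini_entry <- function(ac, tm1_seq, shift = 0L) {
  L <- nchar(tm1_seq)
  row <- data.frame(uniprot_ac = ac, class = "X",
                    sequence = paste0(tm1_seq,
                                      strrep("AAAAAAAAAA", 7)),
                    stringsAsFactors = FALSE)
  row$bw150_idx <- ceiling(L / 2) + shift
  row$tm1_start <- 1L; row$tm1_end <- L
  for (h in 2:7) {
    s <- L + (h - 2) * 10L + 1L
    row[[paste0("bw", h, "50_idx")]] <- s + 5L
    row[[paste0("tm", h, "_start")]] <- s
    row[[paste0("tm", h, "_end")]] <- s + 9L
  }
  row
}

test_that("a sequence is 100% similar to itself and similarity is symmetric", {
  a <- mini_entry("P1", "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(tm_similarity(a, a), 100)
  b <- mini_entry("P2", "ACDEFGHIKLMNPQRSTVWA")
  s_ab <- tm_similarity(a, b)
  expect_equal(s_ab, tm_similarity(b, a))
  expect_gte(s_ab, 0); expect_lte(s_ab, 100)
})

test_that("similarity equals the hand-computed positive-entry fraction", {
  m <- blosum62()
  a <- mini_entry("P1", "ACDEF")
  b <- mini_entry("P2", "ACDEF")
  expect_equal(tm_similarity(a, b, helices = 1), 100)
  g <- mini_entry("P3", "GGGGG")
  # look the five entries up by hand: B62(A,G)=0, (C,G)=-3, (D,G)=-1,
  # (E,G)=-2, (F,G)=-3 -> none positive
  hand <- c(m["A", "G"], m["C", "G"], m["D", "G"], m["E", "G"], m["F", "G"])
  expect_equal(tm_similarity(a, g, helices = 1), 100 * sum(hand > 0) / 5)
  # a mixed case: AAAAA vs ASDEF -> positive at A-A and A-S only
  x <- mini_entry("P4", "AAAAA")
  y <- mini_entry("P5", "ASDEF")
  hand2 <- c(m["A", "A"], m["A", "S"], m["A", "D"], m["A", "E"], m["A", "F"])
  expect_equal(tm_similarity(x, y, helices = 1),
               100 * sum(hand2 > 0) / 5)
})

test_that("columns outside a protein's TM extent are clipped", {
  a <- mini_entry("P1", "ACDEFGHIKL")
  short <- a                                  # same protein, TM1 3 shorter
  short$uniprot_ac <- "P2"
  short$tm1_end <- 7L
  s <- tm_similarity(a, short, helices = 1)
  expect_equal(s, 100)                        # shared extent is identical
  # forcing the full span of `a` clips to the 7 comparable columns
  s2 <- tm_similarity(a, short, helices = 1,
                      tm_cols = list(c(46, 55), NULL, NULL, NULL, NULL,
                                     NULL, NULL))
  expect_equal(s2, 100)
})

test_that("the shift scan peaks at the compensating offset", {
  set.seed(5)
  fam <- make_family(family_spec(n_families = 1, n_members = 6,
                                 sub_prob = 0.05, seed = 31))
  groupA <- fam
  groupB <- fam
  groupB$bw350_idx <- groupB$bw350_idx + 2L     # displaced anchors on TM3
  groupB$uniprot_ac <- paste0(groupB$uniprot_ac, "b")
  scan <- group_shift_scan(groupA, groupB, helix = 3)
  expect_equal(scan$offset[which.max(scan$mean_similarity)], -2)
  # self-comparison peaks at offset zero
  scan0 <- group_shift_scan(groupA, groupB <- transform(groupA,
    uniprot_ac = paste0(uniprot_ac, "b")), helix = 2)
  expect_equal(scan0$offset[which.max(scan0$mean_similarity)], 0)
})

test_that("the best offset does not depend on the substitution matrix", {
  fam <- make_family(family_spec(n_families = 1, n_members = 6,
                                 sub_prob = 0.05, seed = 32))
  shifted <- fam
  shifted$bw550_idx <- shifted$bw550_idx + 3L
  shifted$uniprot_ac <- paste0(shifted$uniprot_ac, "b")
  best <- function(submat) {
    scan <- group_shift_scan(fam, shifted, helix = 5, submat = submat)
    scan$offset[which.max(scan$mean_similarity)]
  }
  expect_equal(best(blosum62()), -3)
  expect_equal(best(substitution_matrix("BLOSUM45")), -3)
  expect_equal(best(substitution_matrix("BLOSUM80")), -3)
})

test_that("group means equal the brute-force double loop", {
  fam <- make_family(family_spec(n_families = 2, n_members = 3,
                                 sub_prob = 0.15, seed = 33))
  ga <- fam[fam$family == 1, ]
  gb <- fam[fam$family == 2, ]
  scan <- group_shift_scan(ga, gb, helix = 4, offsets = 0)
  acc <- c()
  for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb)))
    acc <- c(acc, tm_similarity(ga[i, ], gb[j, ], helices = 4))
  expect_equal(scan$mean_similarity, mean(acc))
  expect_equal(scan$n_pairs, 9)
})

test_that("alignment tables and padded FASTA round-trip", {
  fam <- make_family(family_spec(n_families = 2, n_members = 2, seed = 34))
  f <- withr::local_tempfile(fileext = ".csv")
  write_alignment_table(fam, f)
  back <- read_alignment_table(f)
  expect_equal(back$uniprot_ac, fam$uniprot_ac)
  expect_equal(back$bw350_idx, fam$bw350_idx)
  expect_equal(back$sequence, fam$sequence)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(fam, fa)
  seqs <- Biostrings::readAAStringSet(fa)
  expect_equal(length(seqs), nrow(fam))
  expect_equal(length(unique(Biostrings::width(seqs))), 1)  # aligned columns
  # TM residues survive the padding: the anchor column residue matches
  s1 <- as.character(seqs[[1]])
  expect_equal(nchar(gsub("-", "", s1)), 7L * 26L)
  m <- read_alignment_fasta(fa)
  expect_equal(rownames(m), fam$uniprot_ac)
  expect_equal(paste(m[1, ], collapse = ""), s1)
})

test_that("a custom matrix file loads and validates", {
  m <- blosum62()
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(m, f, quote = FALSE)
  m2 <- read_substitution_matrix(f)
  expect_equal(m2, m, ignore_attr = TRUE)
  bad <- m; bad[1, 2] <- 99
  f2 <- withr::local_tempfile(fileext = ".txt")
  write.table(bad, f2, quote = FALSE)
  expect_error(read_substitution_matrix(f2), "symmetric")
})
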