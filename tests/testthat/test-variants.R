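# Cohort fixture: one family member provides the alignment geometry; variants
# are planted at known BW positions.
cohort_alignment <- function() {
  make_family(family_spec(n_families = 1, n_members = 1, sub_prob = 0,
                          seed = 51))
}

true_wt <- function(al, i, pos) substring(al$sequence[i], pos, pos)

# the alignment geometry without sequences: lets tests plant arbitrary
# wild-type letters without tripping the sequence cross-check
bare <- function(al) { al$sequence <- NULL; al }

test_that("variants map to BW positions, loops map to NA", {
  al <- cohort_alignment()
  anchor3 <- al$bw350_idx[1]
  pos <- c(anchor3, anchor3 - 4L, 1L)
  v <- data.frame(uniprot_ac = rep(al$uniprot_ac[1], 3),
                  position = pos,
                  wt = true_wt(al, 1, pos), mut = "V", annotation = "")
  mapped <- map_variants(v, al)
  expect_false(any(mapped$wt_mismatch))
  expect_equal(mapped$bw, c("3.50", "3.46", NA))
  expect_equal(mapped$helix, c(3L, 3L, NA))
  expect_error(map_variants(data.frame(uniprot_ac = "NOPE", position = 1,
                                       wt = "A", mut = "V"), al),
               "absent")
})

test_that("the five-term score evaluates as in the hand-worked case", {
  al <- cohort_alignment()
  # roster {3.50} with multiplicity 2 on both lists; variant at 3.46, A->V
  roster <- data.frame(bw = "3.50", helix = 3L, index = 50L,
                       multiplicity = 2L)
  al <- bare(al)
  v <- data.frame(uniprot_ac = al$uniprot_ac[1],
                  position = al$bw350_idx[1] - 4L, wt = "A", mut = "V",
                  annotation = "")
  sc <- score_variants(map_variants(v, al), chico = roster, nacho = roster)
  b62_av <- blosum62()["A", "V"]     # equals 0
  expect_equal(sc$score, 4 + 4 - 2 - 2 + b62_av)
  expect_equal(sc$d_nacho, 4)
  expect_equal(sc$mult_chico, 2)
  # variant sitting on both rosters: distance terms vanish
  v0 <- v; v0$position <- al$bw350_idx[1]
  sc0 <- score_variants(map_variants(v0, al), chico = roster, nacho = roster)
  expect_equal(sc0$score, 0 + 0 - 2 - 2 + b62_av)
  # helix without roster residues falls back to the sentinel
  v7 <- v; v7$position <- al$bw750_idx[1]
  sc7 <- score_variants(map_variants(v7, al), chico = roster, nacho = roster)
  expect_equal(sc7$d_nacho, 20)
  expect_equal(sc7$mult_nacho, 0)
})

test_that("score is monotone in distances and multiplicities", {
  al <- bare(cohort_alignment())
  roster1 <- data.frame(bw = "3.50", helix = 3L, index = 50L,
                        multiplicity = 1L)
  roster3 <- data.frame(bw = "3.50", helix = 3L, index = 50L,
                        multiplicity = 3L)
  mk <- function(dist, chico, nacho) {
    v <- data.frame(uniprot_ac = al$uniprot_ac[1],
                    position = al$bw350_idx[1] + dist, wt = "A", mut = "V",
                    annotation = "")
    score_variants(map_variants(v, al), chico, nacho)$score
  }
  expect_lt(mk(1, roster1, roster1), mk(3, roster1, roster1))
  expect_lt(mk(2, roster3, roster1), mk(2, roster1, roster1))
  expect_lt(mk(2, roster1, roster3), mk(2, roster1, roster1))
})

test_that("contact rosters carry per-residue multiplicities", {
  ids <- c("2.45-3.42", "2.42-3.46", "2.42-3.45", "3.44-4.52")
  roster <- contact_roster(ids)
  expect_equal(roster$multiplicity[roster$bw == "2.42"], 2L)
  expect_equal(roster$multiplicity[roster$bw == "4.52"], 1L)
  expect_equal(sum(roster$multiplicity), 2L * length(ids))
  expect_equal(roster$helix, sort(roster$helix))   # sorted by helix
})

test_that("summary satisfies the partition identities on a planted cohort", {
  al <- make_family(family_spec(n_families = 2, n_members = 3, sub_prob = 0,
                                seed = 52))
  al$class <- rep(c("A", "Olfactory"), each = 3)
  chico <- data.frame(bw = c("2.50", "3.50"), helix = c(2L, 3L),
                      index = 50L, multiplicity = 1L)
  nacho <- data.frame(bw = c("3.50", "6.44"), helix = c(3L, 6L),
                      index = c(50L, 44L), multiplicity = 1L)
  set.seed(53)
  n <- 60
  acs <- sample(al$uniprot_ac, n, replace = TRUE)
  pos <- sample(nchar(al$sequence[1]), n, replace = TRUE)
  wt <- substr(al$sequence[match(acs, al$uniprot_ac)], pos, pos)
  v <- data.frame(uniprot_ac = acs, position = pos, wt = wt, mut = "W",
                  annotation = sample(c("", "disease"), n, replace = TRUE))
  sc <- score_variants(map_variants(v, al), chico, nacho)
  s <- summarize_variants(sc)
  g <- function(cat, col = "n") s[[col]][s$category == cat]
  expect_equal(g("all"), n)
  expect_equal(g("tm") + g("non_tm"), g("kept"))
  # roster strata partition the on-roster TM variants
  expect_equal(g("chico_only") + g("both"), g("chico"))
  expect_equal(g("nacho_only") + g("both"), g("nacho"))
  # brute-force tallies of planted membership
  kept <- sc$class != "Olfactory"
  in_tm <- !is.na(sc$helix)
  on_c <- in_tm & !is.na(sc$d_chico) & sc$d_chico == 0
  on_n <- in_tm & !is.na(sc$d_nacho) & sc$d_nacho == 0
  expect_equal(g("tm"), sum(in_tm & kept))
  expect_equal(g("chico"), sum(on_c & kept))
  expect_equal(g("both"), sum(on_c & on_n & kept))
  expect_equal(g("nacho_only"), sum(on_n & !on_c & kept))
  # annotated percentages agree with direct computation
  ann <- sc$annotation != ""
  expect_equal(g("tm", "pct_annotated"),
               round(100 * sum(in_tm & kept & ann) / sum(in_tm & kept), 1))
  # zero variants give an all-zero table
  s0 <- summarize_variants(sc[0, ])
  expect_true(all(s0$n == 0))
  expect_true(all(s0$pct_annotated == 0))
})

test_that("wild-type mismatches are flagged against the table sequence", {
  al <- cohort_alignment()
  wt_true <- substr(al$sequence[1], al$bw350_idx[1], al$bw350_idx[1])
  wt_bad <- setdiff(c("A", "C"), wt_true)[1]
  v <- data.frame(uniprot_ac = al$uniprot_ac[1], position = al$bw350_idx[1],
                  wt = wt_bad, mut = "V", annotation = "")
  expect_warning(mapped <- map_variants(v, al), "disagree")
  expect_true(mapped$wt_mismatch)
})
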