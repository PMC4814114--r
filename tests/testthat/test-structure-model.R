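test_that("PDB round trip reproduces coordinates and helix layout", {
  b <- std_bundle(seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bundle_pdb(b, f)
  b2 <- load_structure(f, chain = "A", annotation = bundle_annotation(b),
                       structure_id = b$structure_id)
  for (h in 1:7) {
    expect_equal(b2$helices[[h]]$resno, b$helices[[h]]$resno)
    expect_equal(b2$helices[[h]]$aa, b$helices[[h]]$aa)
    expect_equal(as.matrix(b2$helices[[h]]$atoms[, c("x", "y", "z")]),
                 as.matrix(b$helices[[h]]$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  # C-alpha coordinates to 1e-3 A
  expect_equal(unname(do.call(rbind, bundle_ca(b2))),
               unname(do.call(rbind, bundle_ca(b))), tolerance = 1e-3)
})

test_that("annotated range outside the chain names the offending helix", {
  b <- std_bundle(seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bundle_pdb(b, f)
  ann <- bundle_annotation(b)
  # a TM3 window in the gap between the real TM2 and TM4 residues
  bad <- tm_annotation(replace(ann$start, 3, 280),
                       replace(ann$end, 3, 295))
  expect_error(load_structure(f, "A", bad), "TM3")
  expect_error(load_structure(f, "B", ann), "chain 'B'")
})

test_that("altloc collapse keeps the best-occupancy atom, ties to altloc A", {
  b <- std_bundle(seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bundle_pdb(b, f)
  lines <- readLines(f)
  atom <- grep("^ATOM", lines)
  # duplicate the first CB of TM1 as altloc A (occ .40) / B (occ .60), and a
  # CA elsewhere as a tie at .50/.50; shift the B copies by 1 A in x
  cb1 <- grep("^ATOM.{8} CB ", lines)[1]
  ca9 <- grep("^ATOM.{8} CA ", lines)[9]
  with_alt <- function(line, alt, occ, dx = 0) {
    substr(line, 17, 17) <- alt
    x <- as.numeric(substr(line, 31, 38)) + dx
    paste0(substr(line, 1, 30), formatC(x, width = 8, format = "f",
                                        digits = 3),
           substr(line, 39, 54), formatC(occ, width = 6, format = "f",
                                         digits = 2),
           substr(line, 61, nchar(line)))
  }
  lines[cb1] <- with_alt(lines[cb1], "A", 0.40)
  lines <- append(lines, with_alt(lines[cb1], "B", 0.60, dx = 1), after = cb1)
  lines[ca9 + 1] <- with_alt(lines[ca9 + 1], "A", 0.50)
  lines <- append(lines, with_alt(lines[ca9 + 1], "B", 0.50, dx = 1),
                  after = ca9 + 1)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f2)
  b2 <- load_structure(f2, "A", bundle_annotation(b))
  # brute-force expectation: one atom per (residue, name), so counts match
  n_expected <- vapply(b$helices, function(h) nrow(h$atoms), integer(1))
  n_got <- vapply(b2$helices, function(h) nrow(h$atoms), integer(1))
  expect_equal(n_got, n_expected)
  # occupancy winner: the B copy of the CB (shifted by +1 in x) was kept
  cb_orig <- b$helices[[1]]$atoms
  cb_new <- b2$helices[[1]]$atoms
  i <- which(cb_orig$name == "CB")[1]
  expect_equal(cb_new$x[cb_new$name == "CB"][1], cb_orig$x[i] + 1,
               tolerance = 1e-3)
  # tie: altloc A (unshifted) wins for the duplicated CA
  ca_a <- bundle_ca(b); ca_b <- bundle_ca(b2)
  expect_equal(unname(ca_b[[1]]), unname(ca_a[[1]]), tolerance = 1e-3)
})

test_that("bundle residue count equals the annotated lengths", {
  b <- std_bundle(seed = 2, lengths = c(20, 24, 30, 26, 22, 28, 25))
  ann <- bundle_annotation(b)
  n <- vapply(b$helices, function(h) length(h$resno), integer(1))
  expect_equal(n, tm_length(ann))
  expect_equal(sum(n), sum(tm_length(ann)))
})

test_that("TM cores extend to the ends of helix runs and no further", {
  ss <- setNames(rep(" ", 60), 1:60)
  ss[as.character(5:33)] <- "H"
  one <- function(lo, hi) {
    # embed the core under test as TM1; park TMs 2..7 far away with H labels
    starts <- c(lo, 100, 200, 300, 400, 500, 600)
    ends <- c(hi, 110, 210, 310, 410, 510, 610)
    ss_far <- setNames(rep("H", 77), unlist(lapply(starts[-1], function(s)
      s + 0:10)))
    extend_tm_by_helix(tm_annotation(starts, ends), c(ss, ss_far))
  }
  # core strictly inside the H run 5..33
  ext <- one(10, 30)
  expect_equal(ext$start[1], 5)
  expect_equal(ext$end[1], 33)
  # core equal to the H run is a fixed point
  ext2 <- one(5, 33)
  expect_equal(c(ext2$start[1], ext2$end[1]), c(5, 33))
  # brute-force scan of the label string for an asymmetric run
  ss3 <- setNames(rep(" ", 60), 1:60)
  ss3[as.character(8:30)] <- "H"
  starts <- c(10, 100, 200, 300, 400, 500, 600)
  ends <- c(30, 110, 210, 310, 410, 510, 610)
  ss_far <- setNames(rep("H", 77), unlist(lapply(starts[-1], function(s)
    s + 0:10)))
  ext3 <- extend_tm_by_helix(tm_annotation(starts, ends), c(ss3, ss_far))
  run <- range(as.integer(names(ss3)[ss3 == "H"]))
  expect_equal(c(ext3$start[1], ext3$end[1]), run)
  expect_equal(c(ext3$start[1], ext3$end[1]), c(8, 30))
  # idempotence
  ext4 <- extend_tm_by_helix(ext3, c(ss3, ss_far))
  expect_equal(ext4, ext3)
  # missing labels inside a core are an error
  expect_error(
    extend_tm_by_helix(tm_annotation(starts, ends), ss3["10"]),
    "missing residues")
})

test_that("DSSP classic format parses into residue labels", {
  f <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    4 A M              0   0  217",
    "    2    5 A K  H  <         0   0  195",
    "    3    6 A L  H  >         0   0   32",
    "    4         !*             0   0    0",
    "    5    8 A V  E            0   0   11"), f)
  d <- read_dssp(f, chain = "A")
  expect_equal(d$resno, c(4L, 5L, 6L, 8L))
  expect_equal(d$ss, c(" ", "H", "H", "E"))
  expect_equal(d$aa, c("M", "K", "L", "V"))
})
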