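#' Substitution matrices
#'
#' `blosum62()` returns the canonical BLOSUM62 matrix (from Biostrings'
#' shipped copy of the NCBI matrix), restricted to the 20 standard amino
#' acids.  `read_substitution_matrix()` loads a user-supplied matrix (e.g.
#' GPCRtm) from a whitespace-separated square table with a header row of
#' amino acids.  Two aligned residues are called *similar* when their matrix
#' entry is positive; percent similarity is the fraction of similar columns.
#'
#' @param name one of the substitution matrices shipped with Biostrings.
#' @return integer matrix with dimnames over the 20 standard amino acids.
#' @export
blosum62 <- function() substitution_matrix("BLOSUM62")

#' @rdname blosum62
#' @export
substitution_matrix <- function(name = c("BLOSUM62", "BLOSUM45", "BLOSUM80",
                                         "BLOSUM100", "PAM250")) {
  name <- match.arg(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)[AA1, AA1]
  check_submat(m)
  m
}

#' @rdname blosum62
#' @param path matrix file.
#' @export
read_substitution_matrix <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, check.names = FALSE,
                            row.names = 1))
  if (!all(AA1 %in% rownames(m)) || !all(AA1 %in% colnames(m)))
    stop("matrix must cover the 20 standard amino acids")
  m <- m[AA1, AA1]
  check_submat(m)
  m
}

check_submat <- function(m) {
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix is not symmetric")
  invisible(m)
}

#' Alignment table (one row per protein)
#'
#' The gap-free TM alignment of a protein is fully determined by seven
#' sequence-index anchors (the residue labeled n.50 on each helix) plus the
#' seven TM ranges.  The table dialect has columns `uniprot_ac`, `class`,
#' `bw150_idx` ... `bw750_idx`, `tm1_start`, `tm1_end`, ..., `tm7_start`,
#' `tm7_end`, and (optionally, required for similarity computations)
#' `sequence`.
#'
#' @param path CSV file.
#' @return data.frame in the dialect above.
#' @export
read_alignment_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_alignment_table(df)
  df
}

#' @rdname read_alignment_table
#' @param entries alignment-table data.frame.
#' @export
write_alignment_table <- function(entries, path) {
  validate_alignment_table(entries)
  write.csv(entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

alignment_cols <- function() {
  c("uniprot_ac", "class", paste0("bw", 1:7, "50_idx"),
    paste0("tm", rep(1:7, each = 2), c("_start", "_end")))
}

validate_alignment_table <- function(df) {
  miss <- setdiff(alignment_cols(), names(df))
  if (length(miss)) stop("alignment table missing columns: ",
                         paste(miss, collapse = ", "))
  for (h in 1:7) {
    a <- df[[paste0("bw", h, "50_idx")]]
    s <- df[[paste0("tm", h, "_start")]]
    e <- df[[paste0("tm", h, "_end")]]
    if (any(s > e)) stop("tm", h, ": start exceeds end")
    if (any(a < s | a > e)) stop("bw", h, "50 anchor outside TM", h, " range")
  }
  invisible(df)
}

entry_field <- function(entry, field) {
  v <- entry[[field]]
  if (is.null(v) || !length(v)) stop("alignment entry lacks ", field)
  v[1]
}

# residue characters of `entry` at BW columns `bw` on helix h; NA outside the
# protein's TM extent or sequence
entry_residues <- function(entry, helix, bw) {
  anchor <- entry_field(entry, paste0("bw", helix, "50_idx"))
  s <- entry_field(entry, paste0("tm", helix, "_start"))
  e <- entry_field(entry, paste0("tm", helix, "_end"))
  seqs <- entry_field(entry, "sequence")
  idx <- anchor + bw - 50L
  ok <- idx >= s & idx <= e & idx >= 1 & idx <= nchar(seqs)
  out <- rep(NA_character_, length(bw))
  out[ok] <- strsplit(substring(seqs, 1, nchar(seqs)), "")[[1]][idx[ok]]
  out
}

#' TM-only percent similarity between two aligned proteins
#'
#' Compares the two sequences column-by-column over the requested BW spans
#' (gapless by construction) and returns 100 times the fraction of columns
#' whose substitution-matrix entry is positive.  Columns where either protein
#' has no residue (outside its TM extent) are clipped from the comparison.
#'
#' @param a,b alignment-table rows (one-row data.frames or lists) with a
#'   `sequence` field.
#' @param tm_cols per-helix BW column spans: list of length 7 of `c(lo, hi)`
#'   BW indices, or `NULL` to use the shared extent of the two entries.
#' @param submat substitution matrix, default [blosum62()].
#' @param helices which helices to include (default all 7).
#' @return percent similarity in `[0, 100]`.
#' @export
tm_similarity <- function(a, b, tm_cols = NULL, submat = blosum62(),
                          helices = 1:7) {
  n_sim <- 0L; n_tot <- 0L
  for (h in helices) {
    span <- if (!is.null(tm_cols)) tm_cols[[h]] else
      shared_span(a, b, h)
    if (is.null(span) || span[1] > span[2]) next
    bw <- span[1]:span[2]
    ra <- entry_residues(a, h, bw)
    rb <- entry_residues(b, h, bw)
    ok <- !is.na(ra) & !is.na(rb) & ra %in% AA1 & rb %in% AA1
    if (!any(ok)) next
    sc <- submat[cbind(ra[ok], rb[ok])]
    n_sim <- n_sim + sum(sc > 0)
    n_tot <- n_tot + sum(ok)
  }
  if (n_tot == 0L) stop("no comparable TM columns between the two entries")
  100 * n_sim / n_tot
}

shared_span <- function(a, b, h) {
  lo <- max(50L + entry_field(a, paste0("tm", h, "_start")) -
              entry_field(a, paste0("bw", h, "50_idx")),
            50L + entry_field(b, paste0("tm", h, "_start")) -
              entry_field(b, paste0("bw", h, "50_idx")))
  hi <- min(50L + entry_field(a, paste0("tm", h, "_end")) -
              entry_field(a, paste0("bw", h, "50_idx")),
            50L + entry_field(b, paste0("tm", h, "_end")) -
              entry_field(b, paste0("bw", h, "50_idx")))
  c(lo, hi)
}

#' Average BW column span per helix over a set of entries
#'
#' The per-class expected TM range: the (rounded) mean BW start and end of
#' each helix across the entries.  Useful as the `tm_cols` argument of
#' [tm_similarity] when comparing proteins to a class.
#'
#' @param entries alignment-table data.frame.
#' @return list of 7 `c(lo, hi)` BW spans.
#' @export
average_tm_cols <- function(entries) {
  lapply(1:7, function(h) {
    lo <- 50L + entries[[paste0("tm", h, "_start")]] -
      entries[[paste0("bw", h, "50_idx")]]
    hi <- 50L + entries[[paste0("tm", h, "_end")]] -
      entries[[paste0("bw", h, "50_idx")]]
    c(round(mean(lo)), round(mean(hi)))
  })
}

#' Group-vs-group similarity scan over anchor shifts of one helix
#'
#' For each offset, group B's anchor on the chosen helix is displaced by that
#' many residues and the mean cross-pair TM similarity on that helix is
#' recomputed.  The offset maximizing the mean similarity indicates the best
#' gapless alignment of the helix between the two groups.  Self-pairs (same
#' accession in both groups) are excluded.
#'
#' @param groupA,groupB alignment-table data.frames.
#' @param helix helix 1..7 to scan.
#' @param offsets integer offsets to try (classic choice `-5:5`).
#' @param tm_cols optional BW span for the helix (list as in [tm_similarity]).
#' @param submat substitution matrix.
#' @return data.frame `offset`, `mean_similarity`, `n_pairs`.
#' @export
group_shift_scan <- function(groupA, groupB, helix, offsets = -5:5,
                             tm_cols = NULL, submat = blosum62()) {
  if (!nrow(groupA) || !nrow(groupB)) stop("both groups must be non-empty")
  acol <- paste0("bw", helix, "50_idx")
  out <- lapply(offsets, function(off) {
    shifted <- groupB
    shifted[[acol]] <- shifted[[acol]] + off
    sims <- c()
    for (i in seq_len(nrow(groupA))) for (j in seq_len(nrow(shifted))) {
      if (groupA$uniprot_ac[i] == shifted$uniprot_ac[j]) next
      s <- tryCatch(
        tm_similarity(groupA[i, ], shifted[j, ], tm_cols = tm_cols,
                      submat = submat, helices = helix),
        error = function(e) NA_real_)
      sims <- c(sims, s)
    }
    data.frame(offset = off, mean_similarity = mean(sims, na.rm = TRUE),
               n_pairs = sum(!is.na(sims)))
  })
  do.call(rbind, out)
}

#' Export the alignment as padded FASTA
#'
#' Writes one aligned record per entry: for each helix the residues at every
#' BW column of `tm_cols`, with `-` where a column lies outside the protein's
#' TM span, so that BW columns line up across the whole file.
#'
#' @param entries alignment-table data.frame with sequences.
#' @param path output FASTA.
#' @param tm_cols per-helix BW spans (default: [average_tm_cols] of the
#'   entries, extended to cover every entry's full extent).
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(entries, path, tm_cols = NULL) {
  if (is.null(tm_cols)) {
    tm_cols <- lapply(1:7, function(h) {
      lo <- 50L + entries[[paste0("tm", h, "_start")]] -
        entries[[paste0("bw", h, "50_idx")]]
      hi <- 50L + entries[[paste0("tm", h, "_end")]] -
        entries[[paste0("bw", h, "50_idx")]]
      c(min(lo), max(hi))
    })
  }
  recs <- vapply(seq_len(nrow(entries)), function(i) {
    paste(vapply(1:7, function(h) {
      bw <- tm_cols[[h]][1]:tm_cols[[h]][2]
      r <- entry_residues(entries[i, ], h, bw)
      r[is.na(r)] <- "-"
      paste(r, collapse = "")
    }, character(1)), collapse = "")
  }, character(1))
  x <- Biostrings::AAStringSet(setNames(recs, entries$uniprot_ac))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @return `read_alignment_fasta`: a character matrix of aligned residues
#'   (rows = proteins, columns = alignment columns, `-` for padding).
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(x))) != 1)
    stop("records have unequal aligned lengths")
  m <- do.call(rbind, strsplit(as.character(x), ""))
  rownames(m) <- names(x)
  m
}
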