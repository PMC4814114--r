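#' Residue roster with contact multiplicities
#'
#' Collapses a contact list (CHICOs, or the changed contacts behind the
#' NACHO residues) to its participating residues, counting for each residue
#' how many roster contacts it belongs to (its multiplicity).
#'
#' @param contacts data.frame with `bw_a`, `bw_b` columns (or an `id`
#'   column of `"n.x-m.y"` strings), or a character vector of such ids.
#' @return data.frame `bw`, `helix`, `index`, `multiplicity`, sorted by helix
#'   then index.
#' @export
contact_roster <- function(contacts) {
  if (is.character(contacts)) {
    parts <- do.call(rbind, strsplit(contacts, "-"))
    bw_all <- c(parts[, 1], parts[, 2])
  } else {
    bw_all <- c(contacts$bw_a, contacts$bw_b)
  }
  tab <- table(bw_all)
  bw <- names(tab)
  pr <- if (length(bw)) bw_parts(bw) else matrix(integer(), ncol = 2)
  df <- data.frame(bw = bw, helix = pr[, 1], index = pr[, 2],
                   multiplicity = as.integer(tab), stringsAsFactors = FALSE)
  df <- df[order(df$helix, df$index), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Map natural variants to BW positions
#'
#' Joins a raw variant table to the alignment table by accession and assigns
#' each variant the BW label of its position, or `NA` when the position falls
#' outside all seven TM ranges (N-terminus, loops, C-terminus).
#'
#' @param variants data.frame with columns `uniprot_ac`, `position` (1-based
#'   sequence index), `wt`, `mut`, and optionally `annotation` (free-text
#'   disease/function note; empty or NA = unannotated).
#' @param alignment alignment-table data.frame (see [read_alignment_table]).
#' @return the variant table with added columns `class`, `helix`, `bw_index`,
#'   `bw` (label or NA) and `wt_mismatch` (TRUE when a `sequence` column is
#'   present and disagrees with `wt`).
#' @export
map_variants <- function(variants, alignment) {
  idx <- match(variants$uniprot_ac, alignment$uniprot_ac)
  if (anyNA(idx))
    stop("accession(s) absent from alignment table: ",
         paste(unique(variants$uniprot_ac[is.na(idx)]), collapse = ", "))
  variants$class <- alignment$class[idx]
  variants$helix <- NA_integer_
  variants$bw_index <- NA_integer_
  for (h in 1:7) {
    s <- alignment[[paste0("tm", h, "_start")]][idx]
    e <- alignment[[paste0("tm", h, "_end")]][idx]
    a <- alignment[[paste0("bw", h, "50_idx")]][idx]
    in_h <- !is.na(s) & variants$position >= s & variants$position <= e
    variants$helix[in_h] <- h
    variants$bw_index[in_h] <- 50L + variants$position[in_h] - a[in_h]
  }
  variants$bw <- ifelse(is.na(variants$helix), NA_character_,
                        sprintf("%d.%d", variants$helix, variants$bw_index))
  if (!is.null(alignment$sequence)) {
    obs <- substr(alignment$sequence[idx], variants$position,
                  variants$position)
    variants$wt_mismatch <- obs != "" & obs != variants$wt
    if (any(variants$wt_mismatch, na.rm = TRUE))
      warning(sum(variants$wt_mismatch, na.rm = TRUE),
              " variant(s) disagree with the table sequence (flagged)")
  }
  variants
}

roster_distance <- function(helix, index, roster, sentinel = 20L) {
  on_h <- roster[roster$helix == helix, , drop = FALSE]
  if (!nrow(on_h)) return(c(dist = sentinel, mult = 0L))
  d <- abs(on_h$index - index)
  k <- which.min(d)
  c(dist = d[k], mult = on_h$multiplicity[k])
}

#' Score variants against the CHICO and NACHO rosters
#'
#' For each TM variant computes its residue distance (|BW-index difference|
#' on the same helix) to the nearest NACHO and nearest CHICO residue, the
#' contact multiplicities at those nearest roster residues, and the priority
#' score
#'
#' `score = d_nacho + d_chico - mult_nacho - mult_chico + submat[wt, mut]`
#'
#' Lower scores flag variants more likely to disrupt the fold or the
#' activation switch.  When a helix carries no roster residue the distance
#' term is set to the sentinel (default 20, beyond any TM length) and the
#' multiplicity to 0.
#'
#' @param variants mapped variants (from [map_variants]).
#' @param chico,nacho rosters from [contact_roster].
#' @param submat substitution matrix for the mutation term.
#' @param sentinel distance used when the variant's helix has no roster
#'   residue.
#' @return the table with added columns `d_nacho`, `mult_nacho`, `d_chico`,
#'   `mult_chico`, `score` (all NA outside the TMs), sorted by score
#'   ascending.
#' @export
score_variants <- function(variants, chico, nacho, submat = blosum62(),
                           sentinel = 20L) {
  n <- nrow(variants)
  variants$d_nacho <- variants$mult_nacho <- NA_integer_
  variants$d_chico <- variants$mult_chico <- NA_integer_
  variants$score <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(variants$helix[i])) next
    dn <- roster_distance(variants$helix[i], variants$bw_index[i], nacho,
                          sentinel)
    dc <- roster_distance(variants$helix[i], variants$bw_index[i], chico,
                          sentinel)
    variants$d_nacho[i] <- dn["dist"]; variants$mult_nacho[i] <- dn["mult"]
    variants$d_chico[i] <- dc["dist"]; variants$mult_chico[i] <- dc["mult"]
    blo <- if (variants$wt[i] %in% AA1 && variants$mut[i] %in% AA1)
      submat[variants$wt[i], variants$mut[i]] else 0
    variants$score[i] <- dn["dist"] + dc["dist"] - dn["mult"] - dc["mult"] +
      blo
  }
  variants[order(variants$score, na.last = TRUE), , drop = FALSE]
}

has_annotation <- function(v) {
  !is.null(v$annotation) & !is.na(v$annotation) & trimws(v$annotation) != ""
}

#' Summary of variant counts by structural category
#'
#' Tabulates, for the whole cohort and for its structural strata, the number
#' of variants, the number carrying a disease/function annotation, and the
#' percentage annotated (1 decimal).  Strata: all variants, TM vs non-TM,
#' on the CHICO roster, CHICO-only, on the NACHO roster, NACHO-only, and on
#' both rosters.  `all`/`tm`/`non_tm` count the full cohort; the remaining
#' rows (and the `tm`/`non_tm` split) can optionally exclude classes such as
#' olfactory/unassigned receptors via `exclude_classes`.
#'
#' @param variants scored variants (from [score_variants]).
#' @param exclude_classes class labels excluded from the TM/roster rows
#'   (default `c("Olfactory", "Unassigned")`).
#' @return data.frame `category`, `n`, `n_annotated`, `pct_annotated`.
#' @export
summarize_variants <- function(variants,
                               exclude_classes = c("Olfactory",
                                                   "Unassigned")) {
  ann <- has_annotation(variants)
  in_tm <- !is.na(variants$helix)
  on_chico <- in_tm & !is.na(variants$d_chico) & variants$d_chico == 0
  on_nacho <- in_tm & !is.na(variants$d_nacho) & variants$d_nacho == 0
  kept <- if (is.null(variants$class)) rep(TRUE, nrow(variants)) else
    !(variants$class %in% exclude_classes)
  row <- function(category, mask) {
    n <- sum(mask); na <- sum(mask & ann)
    data.frame(category = category, n = n, n_annotated = na,
               pct_annotated = round(if (n) 100 * na / n else 0, 1))
  }
  rbind(row("all", rep(TRUE, nrow(variants))),
        row("all_tm", in_tm),
        row("kept", kept),
        row("tm", in_tm & kept),
        row("non_tm", !in_tm & kept),
        row("chico_only", kept & on_chico & !on_nacho),
        row("chico", kept & on_chico),
        row("nacho_only", kept & on_nacho & !on_chico),
        row("nacho", kept & on_nacho),
        row("both", kept & on_chico & on_nacho))
}

#' Read a raw variant CSV
#'
#' Dialect: columns `uniprot_ac`, `position`, `wt`, `mut`, `annotation`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_variants <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("uniprot_ac", "position", "wt", "mut")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
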