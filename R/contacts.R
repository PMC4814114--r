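#' Contact-detection parameters
#'
#' A residue pair on different helices is an inter-helical contact when any
#' two of its heavy atoms lie closer than the sum of their van der Waals radii
#' plus a slack term.  Defaults: 0.6 Angstrom slack and Bondi radii
#' (C 1.70, N 1.55, O 1.52, S 1.80; P 1.80, Se 1.90 for completeness).
#'
#' @param slack distance in Angstrom added to the vdW-radii sum; must be >= 0.
#' @param vdw_radii named numeric vector, element -> radius in Angstrom.
#' @return object of class `contact_params`.
#' @export
contact_params <- function(slack = 0.6,
                           vdw_radii = c(C = 1.70, N = 1.55, O = 1.52,
                                         S = 1.80, P = 1.80, SE = 1.90)) {
  if (slack < 0) stop("slack must be non-negative")
  if (any(vdw_radii <= 0)) stop("vdW radii must be positive")
  structure(list(slack = slack, vdw_radii = vdw_radii),
            class = "contact_params")
}

#' Ballesteros-Weinstein anchors
#'
#' The seven n.50 reference residues (author numbering) that, with gapless
#' TM helices, determine the full BW labeling of a structure: residue r on
#' helix n gets label n.(50 + r - anchor_n).
#'
#' @param index integer vector of length 7: author residue number of each
#'   helix's n.50 residue.
#' @param aa optional one-letter residues at the anchors, for display.
#' @return object of class `bw_anchors`.
#' @export
bw_anchors <- function(index, aa = rep(NA_character_, 7)) {
  index <- as.integer(index)
  if (length(index) != 7L) stop("need 7 anchor indices")
  if (any(is.na(index))) stop("anchor indices contain NA")
  structure(list(index = index, aa = aa), class = "bw_anchors")
}

#' @export
print.bw_anchors <- function(x, ...) {
  lab <- ifelse(is.na(x$aa), x$index, paste0(x$aa, x$index))
  cat("BW n.50 anchors:", paste(sprintf("%d.50=%s", 1:7, lab),
                                collapse = " "), "\n")
  invisible(x)
}

#' BW label of one residue
#'
#' @param anchors a [bw_anchors].
#' @param helix helix number 1..7.
#' @param author_index residue number in author numbering.
#' @param annotation optional [tm_annotation]; when given, residues outside
#'   the helix's TM range raise an error.
#' @return character BW label, e.g. `"3.50"`.
#' @export
bw_label <- function(anchors, helix, author_index, annotation = NULL) {
  if (!helix %in% 1:7) stop("helix must be 1..7")
  if (!is.null(annotation) &&
      (any(author_index < annotation$start[helix]) ||
       any(author_index > annotation$end[helix])))
    stop("residue outside TM", helix, " range")
  sprintf("%d.%d", helix, 50L + author_index - anchors$index[helix])
}

contact_id <- function(bw_a, bw_b) paste(bw_a, bw_b, sep = "-")

#' Detect inter-helical heavy-atom contacts
#'
#' A residue pair (on different helices) is reported as one contact iff any
#' heavy-atom pair across the two residues is closer than the sum of the two
#' atoms' van der Waals radii plus `params$slack`.  Contacts are canonical:
#' the lower-numbered helix comes first, and each residue pair appears once.
#'
#' @param bundle a [tm_bundle].
#' @param anchors a [bw_anchors] for BW labeling, or `NULL` to label by
#'   author numbering only.
#' @param params a [contact_params].
#' @return object of class `contact_set`: a data.frame with columns
#'   `helix_a`, `resno_a`, `helix_b`, `resno_b`, `bw_a`, `bw_b`, `id`,
#'   `min_dist`, `n_atom_pairs`, plus attribute `structure_id`.
#' @export
detect_contacts <- function(bundle, anchors = NULL,
                            params = contact_params()) {
  rad <- params$vdw_radii
  helix_atoms <- lapply(1:7, function(h) {
    a <- bundle$helices[[h]]$atoms
    r <- rad[toupper(a$element)]
    if (any(is.na(r)))
      stop("no vdW radius for element(s): ",
           paste(unique(a$element[is.na(r)]), collapse = ", "),
           " (extend contact_params$vdw_radii)")
    no_heavy <- setdiff(seq_along(bundle$helices[[h]]$resno), unique(a$res))
    if (length(no_heavy))
      warning("TM", h, ": residue(s) without heavy atoms skipped: ",
              paste(bundle$helices[[h]]$resno[no_heavy], collapse = ","))
    list(xyz = as.matrix(a[, c("x", "y", "z")]), res = a$res, rad = unname(r))
  })
  out <- list()
  for (i in 1:6) for (j in (i + 1):7) {
    A <- helix_atoms[[i]]; B <- helix_atoms[[j]]
    d2 <- outer(rowSums(A$xyz^2), rowSums(B$xyz^2), "+") -
      2 * tcrossprod(A$xyz, B$xyz)
    d2[d2 < 0] <- 0
    dmat <- sqrt(d2)
    thr <- outer(A$rad, B$rad, "+") + params$slack
    hit <- which(dmat < thr, arr.ind = TRUE)
    if (!nrow(hit)) next
    ra <- A$res[hit[, 1]]; rb <- B$res[hit[, 2]]
    key <- paste(ra, rb, sep = "_")
    dd <- dmat[hit]
    agg_min <- tapply(dd, key, min)
    agg_n <- tapply(dd, key, length)
    parts <- do.call(rbind, strsplit(names(agg_min), "_"))
    out[[length(out) + 1]] <- data.frame(
      helix_a = i, resno_a = bundle$helices[[i]]$resno[as.integer(parts[, 1])],
      helix_b = j, resno_b = bundle$helices[[j]]$resno[as.integer(parts[, 2])],
      min_dist = as.numeric(agg_min), n_atom_pairs = as.integer(agg_n),
      stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(helix_a = integer(), resno_a = integer(), helix_b = integer(),
               resno_b = integer(), min_dist = numeric(),
               n_atom_pairs = integer())
  df <- df[order(df$helix_a, df$helix_b, df$resno_a, df$resno_b), ,
           drop = FALSE]
  rownames(df) <- NULL
  df <- label_contacts(df, anchors)
  structure(df, class = c("contact_set", "data.frame"),
            structure_id = bundle$structure_id)
}

#' (Re)label a contact table with BW positions
#'
#' Relabeling is cheap because contacts are geometric residue pairs; only the
#' anchor arithmetic changes.  Used heavily by [search_anchors].
#'
#' @param contacts a `contact_set` or plain contact data.frame.
#' @param anchors a [bw_anchors], or `NULL` for author-number labels.
#' @return the table with refreshed `bw_a`, `bw_b`, `id` columns.
#' @export
label_contacts <- function(contacts, anchors) {
  if (is.null(anchors)) {
    contacts$bw_a <- sprintf("%d:%d", contacts$helix_a, contacts$resno_a)
    contacts$bw_b <- sprintf("%d:%d", contacts$helix_b, contacts$resno_b)
  } else {
    contacts$bw_a <- sprintf("%d.%d", contacts$helix_a,
                             50L + contacts$resno_a -
                               anchors$index[contacts$helix_a])
    contacts$bw_b <- sprintf("%d.%d", contacts$helix_b,
                             50L + contacts$resno_b -
                               anchors$index[contacts$helix_b])
  }
  contacts$id <- contact_id(contacts$bw_a, contacts$bw_b)
  contacts
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("Contact set '%s': %d inter-helical contacts\n",
              attr(x, "structure_id") %||% "?", nrow(x)))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Contacts conserved across a panel of structures
#'
#' Counts, for every BW-labeled contact in the union of the input sets, how
#' many sets contain it, and keeps those at or above `min_count`.  All sets
#' must share one BW labeling convention.
#'
#' @param sets list of `contact_set` objects (BW-labeled).
#' @param min_count minimum number of sets a contact must appear in.
#' @return data.frame `id`, `bw_a`, `bw_b`, `count`, sorted by helix pair and
#'   BW indices.
#' @export
conserved_contacts <- function(sets, min_count) {
  if (!length(sets)) stop("no contact sets given")
  ids <- lapply(sets, function(s) unique(s$id))
  tab <- table(unlist(ids))
  keep <- names(tab)[tab >= min_count]
  parts <- do.call(rbind, strsplit(keep, "-"))
  if (is.null(parts)) parts <- matrix(character(), ncol = 2)
  df <- data.frame(id = keep, bw_a = parts[, 1], bw_b = parts[, 2],
                   count = as.integer(tab[keep]), stringsAsFactors = FALSE)
  df[order_bw_pairs(df$bw_a, df$bw_b), , drop = FALSE]
}

bw_parts <- function(bw) {
  p <- do.call(rbind, strsplit(bw, ".", fixed = TRUE))
  matrix(as.integer(p), ncol = 2)
}

order_bw_pairs <- function(bw_a, bw_b) {
  if (!length(bw_a)) return(integer())
  pa <- bw_parts(bw_a); pb <- bw_parts(bw_b)
  order(pa[, 1], pb[, 1], pa[, 2], pb[, 2])
}

#' Cross-class conserved contacts (CHICOs)
#'
#' Restricts a class-A conserved-contact list to the contacts also present in
#' every one of the non-class-A contact sets (or at least `min_count` of
#' them), i.e. the contacts that define the superfamily-wide structural fold.
#'
#' @param classA_conserved data.frame from [conserved_contacts] (needs an
#'   `id` column) or character vector of contact ids.
#' @param non_classA_sets list of `contact_set` objects labeled with the
#'   cross-class anchors.
#' @param min_count how many of the non-class-A sets must contain a contact
#'   (default: all of them).
#' @return the surviving subset, in the same form as `classA_conserved`.
#' @export
chico_contacts <- function(classA_conserved, non_classA_sets,
                           min_count = length(non_classA_sets)) {
  ids <- if (is.character(classA_conserved)) classA_conserved else
    classA_conserved$id
  tab <- table(unlist(lapply(non_classA_sets, function(s) unique(s$id))))
  present <- names(tab)[tab >= min_count]
  keep <- ids %in% present
  if (is.character(classA_conserved)) classA_conserved[keep] else
    classA_conserved[keep, , drop = FALSE]
}

#' Write a contact table as TSV
#' @param contacts a `contact_set`.
#' @param path output file.
#' @export
write_contacts <- function(contacts, path) {
  df <- data.frame(structure_id = attr(contacts, "structure_id") %||% NA,
                   bw_a = contacts$bw_a, bw_b = contacts$bw_b,
                   min_dist = round(contacts$min_dist, 3),
                   n_atom_pairs = contacts$n_atom_pairs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
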