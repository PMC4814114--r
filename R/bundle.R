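#' Seven-helix transmembrane bundle
#'
#' A `tm_bundle` is the package's structural unit: the seven TM helices of one
#' receptor structure, each an ordered run of residues with their heavy atoms.
#' Hydrogens are dropped and alternate locations collapsed at load time, so
#' contact detection can treat every stored atom as a heavy atom.
#'
#' @param structure_id label, e.g. a PDB id.
#' @param helices list of 7 helices; each a list with `resno` (strictly
#'   increasing author residue numbers), `aa` (one-letter residues) and
#'   `atoms` (data.frame `res` (index into `resno`), `name`, `element`,
#'   `x`, `y`, `z`, `occ`).
#' @param protein_id Uniprot accession or `NA`.
#' @param class_label GPCR class label (`"A"`, `"B"`, `"C"`, `"F"`,
#'   `"Adhesion"`, ...).
#' @param state `"active"`, `"inactive"` or `"unknown"`.
#' @return object of class `tm_bundle`.
#' @export
tm_bundle <- function(structure_id, helices, protein_id = NA_character_,
                      class_label = NA_character_, state = "unknown") {
  if (length(helices) != 7L)
    stop("a TM bundle needs exactly 7 helices, got ", length(helices))
  state <- match.arg(state, c("active", "inactive", "unknown"))
  for (h in 1:7) {
    hx <- helices[[h]]
    if (!length(hx$resno))
      stop("TM", h, ": helix is empty")
    if (any(diff(hx$resno) <= 0))
      stop("TM", h, ": residue numbers not strictly increasing")
    if (length(hx$aa) != length(hx$resno))
      stop("TM", h, ": aa/resno length mismatch")
  }
  structure(list(structure_id = structure_id, protein_id = protein_id,
                 class_label = class_label, state = state, helices = helices),
            class = "tm_bundle")
}

#' @export
print.tm_bundle <- function(x, ...) {
  n_res <- vapply(x$helices, function(h) length(h$resno), integer(1))
  n_atoms <- vapply(x$helices, function(h) nrow(h$atoms), integer(1))
  cat(sprintf("TM bundle '%s' (%s, class %s, %s)\n", x$structure_id,
              x$protein_id, x$class_label, x$state))
  cat(sprintf("  %d residues, %d heavy atoms over 7 helices\n",
              sum(n_res), sum(n_atoms)))
  for (h in 1:7)
    cat(sprintf("  TM%d: %d..%d (%d res, %d atoms)\n", h,
                x$helices[[h]]$resno[1],
                x$helices[[h]]$resno[length(x$helices[[h]]$resno)],
                n_res[h], n_atoms[h]))
  invisible(x)
}

#' Per-helix C-alpha coordinates
#'
#' @param bundle a [tm_bundle].
#' @return list of 7 matrices (rows = residues in order, columns x/y/z) with
#'   the residue numbers as rownames.  Residues without a CA atom are skipped.
#' @export
bundle_ca <- function(bundle) {
  lapply(bundle$helices, function(h) {
    a <- h$atoms[h$atoms$name == "CA", , drop = FALSE]
    m <- as.matrix(a[, c("x", "y", "z")])
    rownames(m) <- h$resno[a$res]
    m
  })
}

#' Load a structure file into a TM bundle
#'
#' Reads a PDB file (first model), keeps one chain, drops hydrogens and
#' zero-occupancy atoms, collapses alternate locations (highest occupancy
#' wins; ties go to the alphabetically first altloc), maps modified residues
#' to their parent amino acid (e.g. MSE to M), and slices the chain into the
#' seven annotated TM ranges.
#'
#' @param path PDB file.
#' @param chain chain identifier.
#' @param annotation a [tm_annotation] in the file's author numbering.
#' @inheritParams tm_bundle
#' @return a [tm_bundle].
#' @export
load_structure <- function(path, chain, annotation,
                           structure_id = sub("\\.pdb$", "", basename(path)),
                           protein_id = NA_character_,
                           class_label = NA_character_, state = "unknown") {
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (!chain %in% at$chain)
    stop("chain '", chain, "' not found in ", path)
  at <- at[at$chain == chain, , drop = FALSE]
  # ATOM records plus HETATM of modified residues (MSE etc.)
  at <- at[at$type == "ATOM" |
             (at$type == "HETATM" & at$resid %in% names(MODRES_PARENT)), ,
           drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- sub("^[0-9]*", "", at$elety)     # fall back to atom-name prefix
    elem <- substr(elem, 1, 1)
  }
  elem <- toupper(trimws(elem))
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  elem <- elem[!elem %in% c("H", "D")]
  occ <- at$o; occ[is.na(occ)] <- 1
  keep <- occ > 0
  at <- at[keep, , drop = FALSE]; elem <- elem[keep]; occ <- occ[keep]

  # altloc collapse: one atom per (residue, atom name)
  alt <- at$alt; alt[is.na(alt)] <- ""
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]; elem <- elem[sel]; occ <- occ[sel]

  helices <- vector("list", 7)
  for (h in 1:7) {
    rng <- annotation$start[h]:annotation$end[h]
    sub <- at[at$resno %in% rng, , drop = FALSE]
    if (!nrow(sub))
      stop("TM", h, ": annotated range ", annotation$start[h], "..",
           annotation$end[h], " has no resolvable residues in chain ", chain)
    resno <- sort(unique(sub$resno))
    aa <- vapply(resno, function(r) aa3to1(sub$resid[sub$resno == r][1]),
                 character(1))
    if (any(aa == "X")) {
      warning("TM", h, ": non-standard residues dropped at ",
              paste(resno[aa == "X"], collapse = ","))
      resno <- resno[aa != "X"]; aa <- aa[aa != "X"]
      sub <- sub[sub$resno %in% resno, , drop = FALSE]
    }
    idx <- match(sub$resno, resno)
    helices[[h]] <- list(
      resno = as.integer(resno), aa = aa,
      atoms = data.frame(res = idx, name = trimws(sub$elety),
                         element = elem[match(rownames(sub), rownames(at))],
                         x = sub$x, y = sub$y, z = sub$z,
                         occ = occ[match(rownames(sub), rownames(at))],
                         stringsAsFactors = FALSE))
  }
  tm_bundle(structure_id, helices, protein_id, class_label, state)
}

AA1TO3 <- setNames(names(AA3TO1), AA3TO1)

#' Write a TM bundle as a PDB file
#'
#' Writes the seven helices (in order, one chain) as ATOM records.  Round
#' trip: loading the file back with the bundle's own annotation reproduces
#' all coordinates to the PDB precision of 1e-3 Angstrom.
#'
#' @param bundle a [tm_bundle].
#' @param path output file.
#' @param chain chain id to write.
#' @return `path`, invisibly.
#' @export
write_bundle_pdb <- function(bundle, path, chain = "A") {
  rows <- do.call(rbind, lapply(1:7, function(h) {
    hx <- bundle$helices[[h]]
    data.frame(resno = hx$resno[hx$atoms$res], aa = hx$aa[hx$atoms$res],
               name = hx$atoms$name, element = hx$atoms$element,
               x = hx$atoms$x, y = hx$atoms$y, z = hx$atoms$z,
               o = hx$atoms$occ, stringsAsFactors = FALSE)
  }))
  xyz <- as.numeric(t(as.matrix(rows[, c("x", "y", "z")])))
  n <- nrow(rows)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = rows$resno,
                   resid = unname(AA1TO3[rows$aa]),
                   eleno = seq_len(n),
                   elety = rows$name,
                   chain = rep(chain, n), o = rows$o, b = rep(0, n),
                   elesy = rows$element)
  invisible(path)
}

#' Annotation implied by a bundle's own helices
#' @param bundle a [tm_bundle].
#' @return a [tm_annotation] spanning each helix's first..last residue.
#' @export
bundle_annotation <- function(bundle) {
  tm_annotation(
    start = vapply(bundle$helices, function(h) h$resno[1], integer(1)),
    end = vapply(bundle$helices, function(h) h$resno[length(h$resno)],
                 integer(1)))
}
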