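#' TM extent annotation for the seven transmembrane helices
#'
#' Holds, per helix 1..7, the first and last author residue number (inclusive)
#' of the membrane-spanning segment.  Annotations are an input to the package
#' (OPM-style membrane cores, optionally extended by DSSP helix labels via
#' [extend_tm_by_helix]); they are never derived from coordinates here.
#'
#' @param start,end integer vectors of length 7, author residue numbers.
#' @return An object of class `tm_annotation` with fields `start` and `end`.
#' @examples
#' ann <- tm_annotation(start = c(1, 40, 80, 120, 160, 200, 240),
#'                      end   = c(30, 70, 110, 150, 190, 230, 270))
#' tm_length(ann)
#' @export
tm_annotation <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 7L || length(end) != 7L)
    stop("annotation needs exactly 7 start and 7 end positions")
  if (any(is.na(start)) || any(is.na(end)))
    stop("annotation contains missing positions")
  if (any(start > end))
    stop("helix ", which(start > end)[1], ": start exceeds end")
  # ranges must be ordered 1..7 along the sequence and disjoint
  if (any(end[-7] >= start[-1]))
    stop("TM ranges overlap or are out of order at helix ",
         which(end[-7] >= start[-1])[1] + 1L)
  structure(list(start = start, end = end), class = "tm_annotation")
}

#' @rdname tm_annotation
#' @param x a `tm_annotation`.
#' @export
tm_length <- function(x) x$end - x$start + 1L

#' @export
print.tm_annotation <- function(x, ...) {
  cat("TM annotation (author numbering):\n")
  for (h in 1:7)
    cat(sprintf("  TM%d: %d..%d (%d residues)\n", h, x$start[h], x$end[h],
                x$end[h] - x$start[h] + 1L))
  invisible(x)
}

#' Read/write TM annotation tables
#'
#' CSV dialect: columns `structure_id`, `chain`, `tm1_start`, `tm1_end`, ...,
#' `tm7_start`, `tm7_end`; one row per structure.
#'
#' @param path file path.
#' @return `read_tm_annotations`: a named list of `tm_annotation` objects
#'   (names are structure ids) with a `chain` attribute per element.
#' @export
read_tm_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "chain",
            paste0("tm", rep(1:7, each = 2), c("_start", "_end")))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation CSV missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    ann <- tm_annotation(start = unlist(df[i, paste0("tm", 1:7, "_start")]),
                         end   = unlist(df[i, paste0("tm", 1:7, "_end")]))
    attr(ann, "chain") <- df$chain[i]
    ann
  })
  names(out) <- df$structure_id
  out
}

#' @rdname read_tm_annotations
#' @param annotations named list of `tm_annotation` objects.
#' @param chains character vector of chain ids (recycled if length 1).
#' @export
write_tm_annotations <- function(annotations, path, chains = "A") {
  chains <- rep_len(chains, length(annotations))
  rows <- lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    v <- as.list(c(rbind(a$start, a$end)))
    names(v) <- paste0("tm", rep(1:7, each = 2), c("_start", "_end"))
    c(list(structure_id = names(annotations)[i], chain = chains[i]), v)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a DSSP output file (classic column format)
#'
#' Extracts per-residue secondary-structure codes from the fixed-width residue
#' block that follows the `#  RESIDUE AA STRUCTURE ...` header line.
#'
#' @param path path to a DSSP text output file.
#' @param chain optional chain id filter.
#' @return data.frame with columns `resno` (author numbering), `chain`, `aa`,
#'   `ss` (one-letter DSSP code; `" "` for loop/irregular).
#' @export
read_dssp <- function(path, chain = NULL) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file: residue header not found")
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  keep <- !is.na(resno)                      # chain breaks have blank numbers
  df <- data.frame(resno = resno[keep],
                   chain = substr(body[keep], 12, 12),
                   aa    = substr(body[keep], 14, 14),
                   ss    = substr(body[keep], 17, 17),
                   stringsAsFactors = FALSE)
  if (!is.null(chain)) df <- df[df$chain == chain, , drop = FALSE]
  df
}

#' Extend TM cores to the ends of their alpha helices
#'
#' Each membrane-slab TM core is grown outward in both directions for as long
#' as the secondary-structure label stays helical; ranges are never shrunk.
#' Extension stops before running into the core of a neighboring TM, keeping
#' the seven ranges disjoint.
#'
#' @param annotation a [tm_annotation] giving the membrane cores.
#' @param helix_assignment per-residue labels: either a data.frame with columns
#'   `resno` and `ss` (as from [read_dssp]) or a character vector named by
#'   residue number.
#' @param helix_codes DSSP codes counted as alpha-helical (default `"H"`).
#' @return the extended [tm_annotation].  Idempotent: applying it twice gives
#'   the same result.
#' @export
extend_tm_by_helix <- function(annotation, helix_assignment,
                               helix_codes = "H") {
  if (is.data.frame(helix_assignment)) {
    ss <- setNames(helix_assignment$ss, helix_assignment$resno)
  } else {
    ss <- helix_assignment
    if (is.null(names(ss))) stop("helix_assignment vector must be named by resno")
  }
  is_h <- function(r) {
    v <- ss[as.character(r)]
    !is.na(v) & v %in% helix_codes
  }
  start <- annotation$start; end <- annotation$end
  for (h in 1:7) {
    core <- start[h]:end[h]
    if (any(is.na(ss[as.character(core)])))
      stop("helix_assignment missing residues inside TM", h, " core")
    lo_lim <- if (h > 1) end[h - 1] + 1L else -Inf
    hi_lim <- if (h < 7) start[h + 1] - 1L else Inf
    while (start[h] - 1L >= lo_lim && is_h(start[h] - 1L))
      start[h] <- start[h] - 1L
    while (end[h] + 1L <= hi_lim && is_h(end[h] + 1L))
      end[h] <- end[h] + 1L
  }
  tm_annotation(start, end)
}
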