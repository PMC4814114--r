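#' Number of common BW-labeled contacts between two sets
#'
#' A contact is common when the residue pair carries the same BW labels in
#' both structures, i.e. the intersection of the canonical contact ids.
#'
#' @param setA,setB `contact_set` objects (BW-labeled).
#' @return integer intersection size.
#' @export
count_common <- function(setA, setB) {
  length(intersect(unique(setA$id), unique(setB$id)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation moving `Q` onto `P` minimizing the
#' RMSD of paired rows.
#'
#' @param P,Q n x 3 coordinate matrices, rows paired.
#' @return list with `R` (3x3 rotation applied to centered Q), centroids
#'   `cP`, `cQ`, `rmsd`, and `transform(x)` mapping arbitrary coordinates
#'   from Q's frame into P's frame.
#' @keywords internal
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  s <- svd(crossprod(Q0, P0))
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Q0 %*% R
  list(R = R, cP = cP, cQ = cQ,
       rmsd = sqrt(mean(rowSums((fitted - P0)^2))),
       transform = function(x) sweep(sweep(x, 2, cQ) %*% R, 2, cP, "+"))
}

# BW-paired C-alpha coordinates over the maximal overlapping extent of all
# seven TMs.  Returns list(P, Q, helix) with rows paired.
paired_ca <- function(bundleA, bundleB, anchorsA, anchorsB, helices = 1:7) {
  caA <- bundle_ca(bundleA); caB <- bundle_ca(bundleB)
  P <- NULL; Q <- NULL; hx <- integer()
  for (h in helices) {
    bwA <- as.integer(rownames(caA[[h]])) - anchorsA$index[h] + 50L
    bwB <- as.integer(rownames(caB[[h]])) - anchorsB$index[h] + 50L
    common <- intersect(bwA, bwB)
    if (!length(common)) next
    P <- rbind(P, caA[[h]][match(common, bwA), , drop = FALSE])
    Q <- rbind(Q, caB[[h]][match(common, bwB), , drop = FALSE])
    hx <- c(hx, rep(h, length(common)))
  }
  list(P = P, Q = Q, helix = hx)
}

#' C-alpha RMSD after optimal superposition under a BW pairing
#'
#' Pairs residues with equal BW labels over the maximal overlapping lengths
#' of the 7 TMs, then computes the least-squares rigid-superposition RMSD of
#' the paired C-alpha atoms.
#'
#' @param bundleA,bundleB [tm_bundle] objects.
#' @param anchorsA,anchorsB [bw_anchors] defining each bundle's BW labels.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(bundleA, bundleB, anchorsA, anchorsB) {
  pr <- paired_ca(bundleA, bundleB, anchorsA, anchorsB)
  if (is.null(pr$P) || nrow(pr$P) < 3)
    stop("fewer than 3 paired C-alpha positions")
  kabsch(pr$P, pr$Q)$rmsd
}

# occurrence counts of contact ids over a reference panel
reference_counts <- function(references) {
  tab <- table(unlist(lapply(references, function(s) unique(s$id))))
  setNames(as.integer(tab), names(tab))
}

score_candidate <- function(contacts, anchors, refcount) {
  lab <- label_contacts(contacts, anchors)
  sum(refcount[lab$id], na.rm = TRUE)
}

#' Search BW anchor placements by maximizing common contacts
#'
#' Enumerates gapless shifts of the seven n.50 anchors within `window`
#' residues of the initial guess and scores each candidate by the cumulative
#' number of contact occurrences shared with a reference panel (a contact
#' present in 20 reference sets adds 20).  Candidates whose shifted anchor
#' leaves its TM range are skipped.
#'
#' Because shifting helix n only relabels contacts involving helix n, the
#' default `mode = "coordinate"` scans one helix at a time with the other six
#' fixed and iterates to convergence; `mode = "joint"` enumerates the full
#' product space (practical only for small windows).
#'
#' @param target a [tm_bundle].
#' @param initial a [bw_anchors], the starting guess.
#' @param references list of BW-labeled `contact_set` objects.
#' @param window maximum |shift| per helix (the classic choice is 10).
#' @param params a [contact_params].
#' @param mode `"coordinate"` (default) or `"joint"`.
#' @param annotation [tm_annotation] bounding the anchors; defaults to the
#'   bundle's own helix extents.
#' @param reference_bundle,reference_anchors optional structure used for the
#'   RMSD tie-break column; when absent `rmsd` is `NA`.
#' @param rmsd_top compute RMSD only for this many top-scoring candidates.
#' @param pin named list, helix -> fixed anchor index, overriding the search
#'   for that helix (used to keep an alignment consistent with a homolog);
#'   pinned helices are reported with their pinned anchor.
#' @return data.frame of class `anchor_candidates`: one row per evaluated
#'   candidate with columns `a1..a7` (anchor indices), `s1..s7` (shifts from
#'   `initial`), `score`, `rmsd`, `total_shift`; ranked by score (descending),
#'   then lower RMSD, then smaller total |shift|.  The top row is the
#'   selected alignment.
#' @export
search_anchors <- function(target, initial, references, window = 10,
                           params = contact_params(),
                           mode = c("coordinate", "joint"),
                           annotation = bundle_annotation(target),
                           reference_bundle = NULL, reference_anchors = NULL,
                           rmsd_top = 10, pin = NULL) {
  mode <- match.arg(mode)
  if (window < 0) stop("window must be >= 0")
  contacts <- detect_contacts(target, anchors = NULL, params = params)
  refcount <- reference_counts(references)
  pinned <- rep(NA_integer_, 7)
  if (!is.null(pin))
    pinned[as.integer(names(pin))] <- as.integer(unlist(pin))

  shifts_for <- function(h, around) {
    if (!is.na(pinned[h])) return(pinned[h] - initial$index[h])
    s <- (around - window):(around + window)
    s <- s[abs(s) <= window]
    ok <- initial$index[h] + s >= annotation$start[h] &
      initial$index[h] + s <= annotation$end[h]
    s[ok]
  }
  anchors_of <- function(shift) bw_anchors(initial$index + shift, initial$aa)

  seen <- new.env(parent = emptyenv())
  record <- function(shift, score) {
    key <- paste(shift, collapse = ",")
    assign(key, score, envir = seen)
  }
  score_of <- function(shift) {
    key <- paste(shift, collapse = ",")
    if (exists(key, envir = seen)) return(get(key, envir = seen))
    sc <- score_candidate(contacts, anchors_of(shift), refcount)
    record(shift, sc)
    sc
  }

  if (mode == "joint") {
    grids <- lapply(1:7, function(h) shifts_for(h, 0))
    n_comb <- prod(vapply(grids, length, numeric(1)))
    if (n_comb > 2e5)
      stop("joint mode would enumerate ", format(n_comb, big.mark = ","),
           " candidates; use a smaller window or mode = 'coordinate'")
    grid <- as.matrix(expand.grid(grids))
    for (i in seq_len(nrow(grid))) score_of(grid[i, ])
  } else {
    cur <- integer(7)
    # pinned helices start at their pinned shift
    for (h in 1:7) if (!is.na(pinned[h])) cur[h] <- pinned[h] - initial$index[h]
    repeat {
      changed <- FALSE
      for (h in 1:7) {
        cand <- shifts_for(h, 0)
        best_s <- cur[h]; best_sc <- -Inf
        for (s in cand) {
          trial <- cur; trial[h] <- s
          sc <- score_of(trial)
          if (sc > best_sc || (sc == best_sc && abs(s) < abs(best_s))) {
            best_sc <- sc; best_s <- s
          }
        }
        if (best_s != cur[h]) { cur[h] <- best_s; changed <- TRUE }
      }
      if (!changed) break
    }
  }

  keys <- ls(envir = seen)
  shifts <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  scores <- vapply(keys, function(k) get(k, envir = seen), numeric(1))
  df <- as.data.frame(shifts)
  names(df) <- paste0("s", 1:7)
  for (h in 1:7) df[[paste0("a", h)]] <- initial$index[h] + df[[paste0("s", h)]]
  df$score <- as.integer(scores)
  df$total_shift <- rowSums(abs(shifts))
  df$rmsd <- NA_real_
  df <- df[order(-df$score, df$total_shift), , drop = FALSE]
  if (!is.null(reference_bundle) && !is.null(reference_anchors)) {
    k <- min(rmsd_top, nrow(df))
    for (i in seq_len(k)) {
      cand <- bw_anchors(unlist(df[i, paste0("a", 1:7)]), initial$aa)
      df$rmsd[i] <- tryCatch(
        superpose_rmsd(reference_bundle, target, reference_anchors, cand),
        error = function(e) NA_real_)
    }
    df <- df[order(-df$score, df$rmsd, df$total_shift, na.last = TRUE), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("anchor_candidates", "data.frame")
  df
}

#' Selected anchors from a candidate ranking
#' @param candidates result of [search_anchors].
#' @param initial the [bw_anchors] the search started from (for anchor aa).
#' @return a [bw_anchors] for the top-ranked candidate.
#' @export
selected_anchors <- function(candidates, initial) {
  bw_anchors(unlist(candidates[1, paste0("a", 1:7)]), initial$aa)
}
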