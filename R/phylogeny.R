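#' All-pairs TM similarity matrix
#'
#' @param entries alignment-table data.frame with sequences (rows are
#'   proteins; `uniprot_ac` must be unique).
#' @param tm_cols,submat passed to [tm_similarity].
#' @return symmetric matrix of percent similarities with 100 on the diagonal,
#'   dimnames = accessions.
#' @export
build_similarity_matrix <- function(entries, tm_cols = NULL,
                                    submat = blosum62()) {
  n <- nrow(entries)
  if (n < 2) stop("need at least 2 entries")
  ids <- entries$uniprot_ac
  if (anyDuplicated(ids)) stop("duplicate accessions in entries")
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- tm_similarity(entries[i, ], entries[j, ], tm_cols = tm_cols,
                       submat = submat)
    m[i, j] <- s; m[j, i] <- s
  }
  m
}

# UPGMA (average linkage) with a deterministic tie rule: among all pairs at
# the minimum dissimilarity, merge the pair whose (sorted) representative
# leaf labels are lexicographically smallest.  Returns an hclust object.
upgma_hclust <- function(d, labels) {
  n <- length(labels)
  dm <- as.matrix(d)
  active <- seq_len(n)
  size <- rep(1L, n)
  repr <- labels                  # smallest leaf label per cluster
  node <- -seq_len(n)             # hclust merge codes
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  D <- dm
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL; best_d <- Inf; best_lab <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ai <- active[i]; aj <- active[j]
      dij <- D[ai, aj]
      lab <- sort(c(repr[ai], repr[aj]))
      if (dij < best_d - 1e-12 ||
          (abs(dij - best_d) <= 1e-12 && !is.null(best_lab) &&
           (lab[1] < best_lab[1] ||
            (lab[1] == best_lab[1] && lab[2] < best_lab[2])))) {
        best <- c(ai, aj); best_d <- dij; best_lab <- lab
      }
    }
    a <- best[1]; b <- best[2]
    merge[step, ] <- sort(c(node[a], node[b]))
    height[step] <- best_d
    # average-linkage update into slot a
    for (c in setdiff(active, c(a, b)))
      D[a, c] <- D[c, a] <-
        (size[a] * D[a, c] + size[b] * D[b, c]) / (size[a] + size[b])
    size[a] <- size[a] + size[b]
    repr[a] <- min(repr[a], repr[b])
    node[a] <- step
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge, n), labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "percent dissimilarity"),
            class = "hclust")
}

# greedy sequential variant: seed with the closest pair, then repeatedly
# attach the non-member with the lowest average dissimilarity to the members
sequential_hclust <- function(d, labels) {
  n <- length(labels)
  dm <- as.matrix(d)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  pair <- which(dm == min(dm[upper.tri(dm)]), arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
  # lexicographic tie rule on labels
  lab <- cbind(pmin(labels[pair[, 1]], labels[pair[, 2]]),
               pmax(labels[pair[, 1]], labels[pair[, 2]]))
  pick <- order(lab[, 1], lab[, 2])[1]
  members <- c(pair[pick, 1], pair[pick, 2])
  merge[1, ] <- sort(c(-members[1], -members[2]))
  height[1] <- dm[members[1], members[2]]
  out <- setdiff(seq_len(n), members)
  for (step in 2:(n - 1)) {
    avg <- vapply(out, function(o) mean(dm[o, members]), numeric(1))
    best <- out[order(avg, labels[out])[1]]
    merge[step, ] <- c(-best, step - 1L)
    height[step] <- max(min(avg), height[step - 1])   # keep monotone
    members <- c(members, best)
    out <- setdiff(out, best)
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge, n), labels = labels,
                 method = "sequential", call = match.call(),
                 dist.method = "percent dissimilarity"),
            class = "hclust")
}

hclust_order <- function(merge, n) {
  if (n == 1) return(1L)
  walk <- function(i) {
    if (i < 0) return(-i)
    c(walk(merge[i, 1]), walk(merge[i, 2]))
  }
  walk(nrow(merge))
}

#' Average-linkage tree from a similarity matrix
#'
#' Clusters on dissimilarity `100 - similarity`.  The default is standard
#' UPGMA (average linkage) with a deterministic lexicographic tie rule; the
#' `"sequential"` mode is the greedy variant that grows a single cluster by
#' repeatedly absorbing the outside protein with the lowest average
#' dissimilarity to the current members.
#'
#' Branch lengths follow the ultrametric convention (each merge at height
#' `d/2` from the leaves), so the path length between two leaves equals their
#' cophenetic dissimilarity.
#'
#' @param sim similarity matrix from [build_similarity_matrix].
#' @param method `"upgma"` (default) or `"sequential"`.
#' @return an `ape` `phylo` tree; the underlying `hclust` object (heights =
#'   merge dissimilarities) is attached as attribute `"hclust"`.
#' @export
cluster_tree <- function(sim, method = c("upgma", "sequential")) {
  method <- match.arg(method)
  if (nrow(sim) == 1) {
    tr <- ape::read.tree(text = paste0(rownames(sim)[1], ";"))
    return(tr)
  }
  d <- stats::as.dist(100 - sim)
  labels <- rownames(sim)
  hc <- if (method == "upgma") upgma_hclust(d, labels) else
    sequential_hclust(d, labels)
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Newick output / input
#'
#' @param tree a `phylo` tree (e.g. from [cluster_tree]).
#' @param path file path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
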