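#' Compare contact sets of inactive and active structures
#'
#' Classifies BW-labeled contacts into those present in all structures of
#' both states (`common`), present in at least `min_present` inactive
#' structures and at most `max_other` active ones (`inactive_only`), and the
#' reverse (`active_only`).  The residues participating in the changed
#' contacts are the native activation hot-spot (NACHO) residues.
#'
#' @param inactive,active lists of `contact_set` objects sharing one BW
#'   convention.
#' @param min_present how many structures of a state must contain a contact
#'   for it to count as present in that state (default: all of them).
#' @param max_other how many structures of the opposite state may contain it
#'   (default 0, the strict criterion).
#' @return object of class `state_comparison`: list with data.frames
#'   `common`, `inactive_only`, `active_only` (columns `id`, `bw_a`, `bw_b`)
#'   and `nacho_residues` (columns `bw`, `helix`, `index`, sorted by helix
#'   then index).
#' @export
compare_states <- function(inactive, active,
                           min_present = NULL, max_other = 0) {
  if (!length(inactive) || !length(active))
    stop("need at least one contact set per state")
  min_in <- min_present %||% length(inactive)
  min_ac <- min_present %||% length(active)
  cnt_in <- reference_counts(inactive)
  cnt_ac <- reference_counts(active)
  all_ids <- union(names(cnt_in), names(cnt_ac))
  n_in <- setNames(rep(0L, length(all_ids)), all_ids)
  n_in[names(cnt_in)] <- cnt_in
  n_ac <- setNames(rep(0L, length(all_ids)), all_ids)
  n_ac[names(cnt_ac)] <- cnt_ac

  as_df <- function(ids) {
    parts <- do.call(rbind, strsplit(ids, "-"))
    if (is.null(parts)) parts <- matrix(character(), ncol = 2)
    df <- data.frame(id = ids, bw_a = parts[, 1], bw_b = parts[, 2],
                     stringsAsFactors = FALSE)
    df[order_bw_pairs(df$bw_a, df$bw_b), , drop = FALSE]
  }
  common <- as_df(all_ids[n_in == length(inactive) & n_ac == length(active)])
  inactive_only <- as_df(all_ids[n_in >= min_in & n_ac <= max_other])
  active_only <- as_df(all_ids[n_ac >= min_ac & n_in <= max_other])

  changed <- unique(c(inactive_only$bw_a, inactive_only$bw_b,
                      active_only$bw_a, active_only$bw_b))
  pr <- if (length(changed)) bw_parts(changed) else
    matrix(integer(), ncol = 2)
  roster <- data.frame(bw = changed, helix = pr[, 1], index = pr[, 2],
                       stringsAsFactors = FALSE)
  roster <- roster[order(roster$helix, roster$index), , drop = FALSE]
  rownames(roster) <- NULL
  structure(list(common = common, inactive_only = inactive_only,
                 active_only = active_only, nacho_residues = roster),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf(paste0("State comparison: %d common, %d inactive-only, ",
                     "%d active-only contacts; %d hot-spot residues\n"),
              nrow(x$common), nrow(x$inactive_only), nrow(x$active_only),
              nrow(x$nacho_residues)))
  invisible(x)
}

#' Activation hot-spot report
#'
#' Tabulates the contacts that change between states, together with the
#' deduplicated roster of participating (NACHO) residues and summary counts.
#'
#' @param comparison a [compare_states] result.
#' @return list with `contacts` (columns `category`, `id`, `bw_a`, `bw_b`),
#'   `residues` (the roster with per-residue changed-contact multiplicity),
#'   `n_changed_contacts`, `n_residues`.
#' @export
nacho_report <- function(comparison) {
  ct <- rbind(
    if (nrow(comparison$inactive_only))
      cbind(category = "inactive_only", comparison$inactive_only),
    if (nrow(comparison$active_only))
      cbind(category = "active_only", comparison$active_only))
  if (is.null(ct))
    ct <- data.frame(category = character(), id = character(),
                     bw_a = character(), bw_b = character())
  res <- comparison$nacho_residues
  res$multiplicity <- vapply(res$bw, function(b)
    sum(ct$bw_a == b | ct$bw_b == b), integer(1))
  rownames(ct) <- NULL
  list(contacts = ct, residues = res,
       n_changed_contacts = nrow(ct), n_residues = nrow(res))
}
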