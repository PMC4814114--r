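#' Fit a helix axis
#'
#' Second differences of consecutive C-alpha positions point radially inward
#' on an ideal helix, so each residue's local helix-center can be recovered
#' from them; the axis is the least-squares line (principal component)
#' through those center estimates.  This is exact for ideal helical geometry
#' of any length, unlike a principal component of the raw C-alpha cloud,
#' which is biased by the unbalanced circular phase.  The axis sign points
#' from the intracellular toward the extracellular side: along increasing
#' residue order for even-numbered TMs, against it for odd-numbered TMs
#' (TM1 enters from the extracellular side).
#'
#' @param xyz n x 3 matrix of C-alpha coordinates in residue order (n >= 4).
#' @param helix helix number 1..7 used for the parity convention; `NULL`
#'   orients the axis along increasing residue order.
#' @return object of class `helix_axis`: list `direction` (unit 3-vector)
#'   and `centroid` (mean C-alpha position).
#' @export
fit_axis <- function(xyz, helix = NULL) {
  if (nrow(xyz) < 4) stop("need at least 4 C-alpha positions")
  n <- nrow(xyz)
  v <- diff(xyz)                      # bond vectors
  w <- diff(v)                        # second differences, radially inward
  wn <- sqrt(rowSums(w^2))
  if (any(wn < 1e-9)) stop("degenerate (collinear) geometry")
  what <- w / wn
  # turn angle per residue from successive inward directions
  cosg <- sum(what[-nrow(what), ] * what[-1, ]) / (nrow(what) - 1)
  cosg <- max(-1, min(1, cosg))
  # |w| = 4 r sin^2(gamma/2) recovers the helix radius
  r <- mean(wn) / (4 * ((1 - cosg) / 2))
  centers <- xyz[2:(n - 1), , drop = FALSE] + r * what
  ctr_c <- colMeans(centers)
  a <- svd(sweep(centers, 2, ctr_c), nu = 0, nv = 1)$v[, 1]
  seq_dir <- xyz[n, ] - xyz[1, ]
  if (sum(a * seq_dir) < 0) a <- -a
  if (!is.null(helix) && helix %% 2 == 1) a <- -a
  structure(list(direction = a, centroid = colMeans(xyz)), class = "helix_axis")
}

rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# minimal rotation mapping unit vector u onto unit vector v
rotation_between <- function(u, v) {
  c_ <- sum(u * v)
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- p - sum(p * u) * u
    return(rotation_about(w, 180))
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Rigid-body decomposition of one helix's movement between two structures
#'
#' After (optionally) superposing bundle B onto bundle A over all BW-paired
#' TM C-alpha atoms, the movement of the chosen helix from A to B is broken
#' into: translation of the centroid along A's helix axis (`t_axial`, signed,
#' positive toward the extracellular side) and perpendicular to it
#' (`t_perp`, magnitude); the angle between the two helix axes (`tilt`); the
#' residual rotation about the axis that best maps the paired C-alpha atoms
#' after removing translation and tilt (`spin`, signed); and the RMSD left
#' after the full per-helix rigid fit (`residual_rmsd`).
#'
#' @param bundleA,bundleB [tm_bundle] objects.
#' @param anchorsA,anchorsB [bw_anchors] pairing the residues.
#' @param helix helix 1..7 to decompose.
#' @param superpose superpose B onto A over the whole TM bundle first
#'   (default TRUE; set FALSE when the bundles already share a frame).
#' @return object of class `helix_move`: list `t_axial`, `t_perp`, `tilt`
#'   (degrees, in `[0, 180]`), `spin` (degrees, in `(-180, 180]`),
#'   `residual_rmsd`, `n_paired`.
#' @export
decompose_move <- function(bundleA, bundleB, anchorsA, anchorsB, helix,
                           superpose = TRUE) {
  pr_all <- paired_ca(bundleA, bundleB, anchorsA, anchorsB)
  if (superpose) {
    fit <- kabsch(pr_all$P, pr_all$Q)
    Qall <- fit$transform(pr_all$Q)
  } else {
    Qall <- pr_all$Q
  }
  sel <- pr_all$helix == helix
  if (sum(sel) < 4) stop("fewer than 4 paired residues on TM", helix)
  P <- pr_all$P[sel, , drop = FALSE]
  Q <- Qall[sel, , drop = FALSE]

  axA <- fit_axis(P, helix)
  axB <- fit_axis(Q, helix)
  t_vec <- axB$centroid - axA$centroid
  t_axial <- sum(t_vec * axA$direction)
  t_perp <- sqrt(max(sum(t_vec^2) - t_axial^2, 0))
  cosang <- max(-1, min(1, sum(axA$direction * axB$direction)))
  tilt <- acos(cosang) * 180 / pi

  # remove translation and tilt, then solve the axial rotation
  P0 <- sweep(P, 2, axA$centroid)
  Q0 <- sweep(Q, 2, axB$centroid) %*% t(rotation_between(axB$direction,
                                                         axA$direction))
  a <- axA$direction
  proj <- function(x) x - outer(drop(x %*% a), a)
  Pp <- proj(P0); Qp <- proj(Q0)
  cross_sum <- sum(a[1] * (Pp[, 2] * Qp[, 3] - Pp[, 3] * Qp[, 2]) +
                   a[2] * (Pp[, 3] * Qp[, 1] - Pp[, 1] * Qp[, 3]) +
                   a[3] * (Pp[, 1] * Qp[, 2] - Pp[, 2] * Qp[, 1]))
  dot_sum <- sum(Pp * Qp)
  spin <- atan2(cross_sum, dot_sum) * 180 / pi
  if (spin <= -180) spin <- spin + 360

  residual_rmsd <- kabsch(P, Q)$rmsd
  structure(list(t_axial = t_axial, t_perp = t_perp, tilt = tilt,
                 spin = spin, residual_rmsd = residual_rmsd,
                 n_paired = sum(sel)),
            class = "helix_move")
}

#' @export
print.helix_move <- function(x, ...) {
  cat(sprintf(paste0("Helix move: t_axial %.3f A, t_perp %.3f A, ",
                     "tilt %.2f deg, spin %.2f deg, residual RMSD %.3f A ",
                     "(%d paired residues)\n"),
              x$t_axial, x$t_perp, x$tilt, x$spin, x$residual_rmsd,
              x$n_paired))
  invisible(x)
}

#' Per-helix move table for a structure pair
#'
#' Runs [decompose_move] for all seven helices and, when sequences are
#' available in `entries`, attaches the per-helix TM similarity, mirroring
#' the scatter data of move magnitude against sequence similarity.
#'
#' @inheritParams decompose_move
#' @param entryA,entryB optional alignment-table rows for the similarity
#'   column.
#' @return data.frame with one row per helix: `helix`, `similarity` (NA
#'   without entries), `t_axial`, `t_perp`, `tilt`, `spin`,
#'   `residual_rmsd`, `n_paired`.
#' @export
helix_move_table <- function(bundleA, bundleB, anchorsA, anchorsB,
                             entryA = NULL, entryB = NULL,
                             superpose = TRUE) {
  rows <- lapply(1:7, function(h) {
    mv <- decompose_move(bundleA, bundleB, anchorsA, anchorsB, h,
                         superpose = superpose)
    sim <- if (!is.null(entryA) && !is.null(entryB))
      tm_similarity(entryA, entryB, helices = h) else NA_real_
    data.frame(helix = h, similarity = sim, t_axial = mv$t_axial,
               t_perp = mv$t_perp, tilt = mv$tilt, spin = mv$spin,
               residual_rmsd = mv$residual_rmsd, n_paired = mv$n_paired)
  })
  do.call(rbind, rows)
}
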