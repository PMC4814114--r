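#' Specification for an idealized 7-helix bundle
#'
#' The generator arranges seven ideal alpha helices (1.5 Angstrom rise and
#' 100 degrees of phase per residue for the C-alpha trace, plus a radially
#' displaced CB pseudo-atom for side-chain bulk) on a ring.  Helix direction
#' alternates so odd-numbered TMs run extracellular to intracellular along
#' the sequence, as in a receptor.  Geometry is deterministic given the seed.
#'
#' @param lengths residue count per helix (length 7 or scalar; >= 10).
#' @param ring_radius radius of the ring of helix centers, Angstrom.  The
#'   default 6.5 makes a 26-residue bundle carry on the order of 200
#'   inter-helical contacts, the density observed in real receptor
#'   structures; with only two heavy atoms per residue the ring must sit
#'   tighter than a real bundle to reach that density.
#' @param helix_radius C-alpha helix radius, Angstrom.
#' @param cb_offset extra radial distance of the CB pseudo-atom, Angstrom.
#' @param tilts per-helix tilt toward the bundle axis, degrees.
#' @param phases per-helix starting phase, degrees.
#' @param sequences optional character vector of 7 sequences (defaults to
#'   seeded random sequences of the right lengths).
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @param seed integer seed controlling sequences and noise.
#' @param start_resno author residue number of each helix's first residue
#'   (default `h * 100 + 1`).
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(lengths = 26, ring_radius = 6.5, helix_radius = 2.3,
                        cb_offset = 1.5, tilts = 0, phases = NULL,
                        sequences = NULL, noise_sigma = 0, seed = 1,
                        start_resno = NULL) {
  lengths <- rep_len(as.integer(lengths), 7)
  if (any(lengths < 10)) stop("helix lengths must be >= 10")
  tilts <- rep_len(tilts, 7)
  if (is.null(phases)) phases <- (0:6) * 40
  phases <- rep_len(phases, 7)
  if (is.null(start_resno)) start_resno <- (1:7) * 100L + 1L
  # reject overlapping helices: ring chord between adjacent centers
  chord <- 2 * ring_radius * sin(pi / 7)
  if (chord < 4) stop("helix centers closer than 4 Angstrom; enlarge ring")
  structure(list(lengths = lengths, ring_radius = ring_radius,
                 helix_radius = helix_radius, cb_offset = cb_offset,
                 tilts = tilts, phases = phases, sequences = sequences,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 start_resno = as.integer(start_resno)),
            class = "bundle_spec")
}

#' Generate an idealized TM bundle
#'
#' @param spec a [bundle_spec].
#' @param structure_id label for the bundle.
#' @param state conformational state label.
#' @return a [tm_bundle].  The BW anchors placed at each helix's middle
#'   residue are attached as attribute `"anchors"` (a [bw_anchors]).
#' @export
make_bundle <- function(spec, structure_id = "synthetic", state = "unknown") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  seqs <- spec$sequences %||% vapply(spec$lengths, function(L)
    paste(sample(AA1, L, replace = TRUE), collapse = ""), character(1))
  helices <- vector("list", 7)
  for (h in 1:7) {
    L <- spec$lengths[h]
    ang <- 2 * pi * (h - 1) / 7
    center <- c(spec$ring_radius * cos(ang), spec$ring_radius * sin(ang), 0)
    # direction: odd TMs run +z -> -z along the sequence
    d <- if (h %% 2 == 1) c(0, 0, -1) else c(0, 0, 1)
    u <- c(cos(ang), sin(ang), 0)            # radial, points outward
    v <- vcross(d, u)
    phi <- (spec$phases[h] + (0:(L - 1)) * 100) * pi / 180
    zz <- ((0:(L - 1)) - (L - 1) / 2) * 1.5
    ca <- t(vapply(seq_len(L), function(k)
      center + spec$helix_radius * (cos(phi[k]) * u + sin(phi[k]) * v) +
        zz[k] * d, numeric(3)))
    cb <- t(vapply(seq_len(L), function(k)
      center + (spec$helix_radius + spec$cb_offset) *
        (cos(phi[k]) * u + sin(phi[k]) * v) + zz[k] * d, numeric(3)))
    if (spec$tilts[h] != 0) {
      R <- rotation_about(v, spec$tilts[h])
      ca <- sweep(sweep(ca, 2, center) %*% t(R), 2, center, "+")
      cb <- sweep(sweep(cb, 2, center) %*% t(R), 2, center, "+")
    }
    if (spec$noise_sigma > 0) {
      ca <- ca + matrix(rnorm(3 * L, 0, spec$noise_sigma), ncol = 3)
      cb <- cb + matrix(rnorm(3 * L, 0, spec$noise_sigma), ncol = 3)
    }
    resno <- spec$start_resno[h] + 0:(L - 1)
    aa <- strsplit(seqs[h], "")[[1]]
    gly <- aa == "G"                          # glycine has no CB
    atoms <- data.frame(res = seq_len(L), name = "CA", element = "C",
                        x = ca[, 1], y = ca[, 2], z = ca[, 3], occ = 1)
    if (any(!gly))
      atoms <- rbind(atoms,
        data.frame(res = which(!gly), name = "CB", element = "C",
                   x = cb[!gly, 1], y = cb[!gly, 2], z = cb[!gly, 3],
                   occ = 1))
    atoms <- atoms[order(atoms$res, atoms$name), , drop = FALSE]
    rownames(atoms) <- NULL
    helices[[h]] <- list(resno = resno, aa = aa, atoms = atoms)
  }
  b <- tm_bundle(structure_id, helices, state = state)
  attr(b, "anchors") <- bundle_anchors_mid(b)
  b
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Anchors at each helix's middle residue
#' @param bundle a [tm_bundle].
#' @return a [bw_anchors].
#' @export
bundle_anchors_mid <- function(bundle) {
  idx <- vapply(bundle$helices, function(h)
    h$resno[ceiling(length(h$resno) / 2)], integer(1))
  aa <- vapply(bundle$helices, function(h)
    h$aa[ceiling(length(h$resno) / 2)], character(1))
  bw_anchors(idx, aa)
}

#' Shift a bundle's author numbering
#'
#' Coordinates are untouched; only residue numbers move.  Exercises the
#' anchor search: renumbering helix n by `+k` means the correct anchor lies
#' `k` residues above the stale one.
#'
#' @param bundle a [tm_bundle].
#' @param offsets integer vector of 7 per-helix offsets added to the author
#'   numbering.
#' @return the renumbered [tm_bundle].
#' @export
renumber_bundle <- function(bundle, offsets) {
  offsets <- rep_len(as.integer(offsets), 7)
  for (h in 1:7)
    bundle$helices[[h]]$resno <- bundle$helices[[h]]$resno + offsets[h]
  if (!is.null(attr(bundle, "anchors"))) {
    a <- attr(bundle, "anchors")
    attr(bundle, "anchors") <- bw_anchors(a$index + offsets, a$aa)
  }
  bundle
}

#' Apply per-helix rigid perturbations
#'
#' Each helix may be translated along its own axis (`t_axial`, toward the
#' extracellular side per the axis convention of [fit_axis]), translated
#' radially outward from the bundle center (`t_perp`), tilted about the
#' in-plane tangent through its centroid (`tilt`, degrees) and rotated about
#' its own axis (`spin`, degrees).  A `moves` element of `NULL` leaves that
#' helix untouched.
#'
#' @param bundle a [tm_bundle].
#' @param moves list of up to 7 elements; each `NULL` or a list with any of
#'   `t_axial`, `t_perp`, `tilt`, `spin` (numbers; defaults 0).
#' @return the perturbed [tm_bundle].
#' @export
perturb_bundle <- function(bundle, moves) {
  ca <- bundle_ca(bundle)
  for (h in seq_along(moves)) {
    mv <- moves[[h]]
    if (is.null(mv)) next
    ax <- fit_axis(ca[[h]], h)
    a <- ax$direction; ctr <- ax$centroid
    radial <- ctr - c(0, 0, ctr[3])
    radial <- radial - sum(radial * a) * a
    radial <- radial / sqrt(sum(radial^2))
    tangent <- vcross(a, radial)
    R <- diag(3)
    if (!is.null(mv$spin) && mv$spin != 0)
      R <- rotation_about(a, mv$spin) %*% R
    if (!is.null(mv$tilt) && mv$tilt != 0)
      R <- rotation_about(tangent, mv$tilt) %*% R
    shift <- (mv$t_axial %||% 0) * a + (mv$t_perp %||% 0) * radial
    at <- bundle$helices[[h]]$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + shift, "+")
    bundle$helices[[h]]$atoms[, c("x", "y", "z")] <- xyz
  }
  bundle
}

#' Apply one rigid transform to a whole bundle
#'
#' @param bundle a [tm_bundle].
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector.
#' @return the transformed [tm_bundle].
#' @export
transform_bundle <- function(bundle, R = diag(3), t = c(0, 0, 0)) {
  for (h in 1:7) {
    at <- bundle$helices[[h]]$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    bundle$helices[[h]]$atoms[, c("x", "y", "z")] <-
      sweep(xyz, 2, t, "+")
  }
  bundle
}

#' Specification for a synthetic sequence family set
#'
#' Each family descends from one ancestor sequence; members substitute each
#' site independently with probability `sub_prob` (to a uniformly chosen
#' different amino acid).  All members share the ancestors' TM layout:
#' helices of `tm_length` residues separated by `loop_length`-residue loops,
#' anchors at the helix midpoints.
#'
#' @param n_families number of families.
#' @param n_members members per family.
#' @param sub_prob per-site substitution probability in `[0, 1]`.
#' @param tm_length residues per TM helix.
#' @param loop_length residues between TMs (and at both termini).
#' @param seed integer seed.
#' @param ancestors optional character vector of full-length ancestor
#'   sequences (overrides `n_families`).
#' @return object of class `family_spec`.
#' @export
family_spec <- function(n_families = 4, n_members = 8, sub_prob = 0.1,
                        tm_length = 26, loop_length = 5, seed = 1,
                        ancestors = NULL) {
  if (sub_prob < 0 || sub_prob > 1) stop("sub_prob must be in [0, 1]")
  structure(list(n_families = if (is.null(ancestors)) n_families else
    length(ancestors), n_members = n_members,
    sub_prob = sub_prob, tm_length = as.integer(tm_length),
    loop_length = as.integer(loop_length), seed = as.integer(seed),
    ancestors = ancestors), class = "family_spec")
}

#' Generate a synthetic sequence family set
#'
#' @param spec a [family_spec].
#' @return alignment-table data.frame (dialect of [read_alignment_table],
#'   with `sequence`) with one row per member plus columns `family` and
#'   `member`; accessions are `F<f>M<m>`, class labels `FAM<f>`.
#' @export
make_family <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  L_tm <- spec$tm_length; L_loop <- spec$loop_length
  total <- 7 * L_tm + 8 * L_loop
  anc <- spec$ancestors %||% vapply(seq_len(spec$n_families), function(f)
    paste(sample(AA1, total, replace = TRUE), collapse = ""), character(1))
  tm_start <- L_loop + 1L + (0:6) * (L_tm + L_loop)
  tm_end <- tm_start + L_tm - 1L
  anchor <- tm_start + (ceiling(L_tm / 2) - 1L)
  rows <- list()
  for (f in seq_along(anc)) {
    anc_chars <- strsplit(anc[f], "")[[1]]
    for (m in seq_len(spec$n_members)) {
      chars <- anc_chars
      hit <- runif(length(chars)) < spec$sub_prob
      if (any(hit))
        chars[hit] <- vapply(chars[hit], function(a)
          sample(setdiff(AA1, a), 1), character(1))
      row <- data.frame(uniprot_ac = sprintf("F%dM%d", f, m),
                        class = sprintf("FAM%d", f),
                        family = f, member = m,
                        sequence = paste(chars, collapse = ""),
                        stringsAsFactors = FALSE)
      for (h in 1:7) {
        row[[paste0("bw", h, "50_idx")]] <- anchor[h]
        row[[paste0("tm", h, "_start")]] <- tm_start[h]
        row[[paste0("tm", h, "_end")]] <- tm_end[h]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
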