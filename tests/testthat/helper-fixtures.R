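# Shared fixtures and independent oracles for the test suite.

# A compact standard bundle: deterministic, ~200 contacts at the default ring.
std_bundle <- function(seed = 7, ...) {
  make_bundle(bundle_spec(seed = seed, ...), structure_id = paste0("syn", seed))
}

# Brute-force O(N^2) contact oracle: loops over every heavy-atom pair of every
# residue pair on different helices, no vectorization shared with the package.
brute_force_contacts <- function(bundle, params = contact_params()) {
  rad <- params$vdw_radii
  out <- character()
  for (i in 1:6) for (j in (i + 1):7) {
    hi <- bundle$helices[[i]]; hj <- bundle$helices[[j]]
    for (ri in seq_along(hi$resno)) for (rj in seq_along(hj$resno)) {
      ai <- hi$atoms[hi$atoms$res == ri, , drop = FALSE]
      aj <- hj$atoms[hj$atoms$res == rj, , drop = FALSE]
      hit <- FALSE
      for (u in seq_len(nrow(ai))) {
        for (v in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[u] - aj$x[v])^2 + (ai$y[u] - aj$y[v])^2 +
                      (ai$z[u] - aj$z[v])^2)
          if (d < rad[[ai$element[u]]] + rad[[aj$element[v]]] + params$slack) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (hit) out <- c(out, sprintf("%d:%d-%d:%d", i, hi$resno[ri],
                                     j, hj$resno[rj]))
    }
  }
  sort(out)
}

contact_keys <- function(cs) {
  sort(sprintf("%d:%d-%d:%d", cs$helix_a, cs$resno_a, cs$helix_b, cs$resno_b))
}

# Independent superposition oracle: Horn's closed-form quaternion method.
quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Q0, P0)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(e2, 0))
}

random_rotation <- function() {
  grossalign:::rotation_about(rnorm(3), runif(1, 0, 360))
}

# Minimal two-residue toy bundle whose TM1/TM2 carry single atoms at an exact
# center distance `d`; the other five helices are parked far away.
toy_distance_bundle <- function(d, element = "C") {
  helices <- lapply(1:7, function(h) {
    x0 <- if (h == 1) 0 else if (h == 2) d else 1000 * h
    resno <- 10L * h + 0:9
    list(resno = resno, aa = rep("A", 10),
         atoms = data.frame(res = 1:10, name = "CA", element = element,
                            x = x0 + c(0, rep(500, 9)),
                            y = 100 * h * c(0, rep(0, 9)) + c(0, 1:9 * 50),
                            z = 0, occ = 1))
  })
  # place residue 1 of TM1 at origin and residue 1 of TM2 at (d, 0, 0); all
  # other residues are hundreds of Angstroms away from everything
  tm_bundle("toy", helices)
}
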