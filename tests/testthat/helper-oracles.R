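# Independent oracles used only by tests; none of these call package internals.

# brute-force minimum-image distance by enumerating all 27 neighbour images
oracle_min_image <- function(p, q, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- p - (q + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# Horn's quaternion method for the optimal proper rotation of X onto Y
# (closed-form eigenvector solution; no SVD, independent of kabsch())
oracle_horn_rotation <- function(X, Y, w = NULL) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  Xc <- sweep(X, 2, colSums(X * w))
  Yc <- sweep(Y, 2, colSums(Y * w))
  S <- t(Xc * w) %*% Yc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2),
    3, 3, byrow = TRUE)
}

# naive O(residues x lipid particles) contact counter for one frame.
# mode "min_particle": residue contacts iff min pair distance < cutoff;
# mode "com": residue COM to per-lipid COM distance < cutoff.
oracle_contacts_frame <- function(top, xyz, box, residues, target_rows,
                                  cutoff, mode = "min_particle",
                                  per_lipid_count = FALSE) {
  p <- top$particles
  lip_ids <- unique(p$resid[target_rows])
  out <- integer(length(residues))
  for (r in seq_along(residues)) {
    rrows <- which(p$species == "protein" & p$resid == residues[r])
    hits <- 0L
    for (lip in lip_ids) {
      lrows <- target_rows[p$resid[target_rows] == lip]
      in_contact <- FALSE
      if (mode == "min_particle") {
        for (i in rrows) for (j in lrows) {
          if (oracle_min_image(xyz[i, ], xyz[j, ], box) < cutoff) {
            in_contact <- TRUE
          }
        }
      } else {
        rm <- p$mass[rrows]; lm <- p$mass[lrows]
        rcom <- colSums(xyz[rrows, , drop = FALSE] * rm) / sum(rm)
        lcom <- colSums(xyz[lrows, , drop = FALSE] * lm) / sum(lm)
        in_contact <- oracle_min_image(rcom, lcom, box) < cutoff
      }
      if (in_contact) hits <- hits + 1L
    }
    out[r] <- if (per_lipid_count) hits else as.integer(hits > 0)
  }
  out
}

# naive triple-loop hydrogen-bond counter for one frame
oracle_hbonds_frame <- function(xyz, box, donors, hydrogen_map, acceptors,
                                d_max, a_max) {
  n <- 0L
  for (d in donors) {
    for (a in acceptors) {
      if (a == d) next
      if (oracle_min_image(xyz[d, ], xyz[a, ], box) > d_max) next
      for (h in hydrogen_map[[as.character(d)]]) {
        # H-D-A angle via the law of cosines on minimum-image vectors
        vda <- xyz[a, ] - xyz[d, ]; vda <- vda - box * round(vda / box)
        vdh <- xyz[h, ] - xyz[d, ]; vdh <- vdh - box * round(vdh / box)
        ang <- acos(max(-1, min(1, sum(vda * vdh) /
                                  sqrt(sum(vda^2) * sum(vdh^2))))) * 180 / pi
        if (ang <= a_max) { n <- n + 1L; break }
      }
    }
  }
  n
}
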