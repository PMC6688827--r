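#' Dimer hinge-angle series
#'
#' Per frame, the planar angle at the vertex selection's COM between the two
#' arm selections' COMs.  Default anchors follow the hinge metric for the
#' side-by-side kinase dimer: catalytic lysine (residue 182) of subunit A,
#' vertex residue 29 of subunit A, and the catalytic lysine of subunit B —
#' addressed by residue and subunit rather than build-specific atom serial
#' numbers; restrict with `and name CA` on atomistic systems.
#'
#' @param traj a [trajectory()]
#' @param sel_armA,sel_vertex,sel_armB selections (expressions or indices)
#' @return object of class `angle_series`: list of `times` (ns) and `theta`
#'   (degrees in `[0, 180]`, `NA` for frames with coincident anchors)
#' @export
hinge_angle_series <- function(traj,
                               sel_armA = "subunit A and resid 182",
                               sel_vertex = "subunit A and resid 29",
                               sel_armB = "subunit B and resid 182") {
  top <- traj$topology
  a <- resolve_selection(top, sel_armA)
  v <- resolve_selection(top, sel_vertex)
  b <- resolve_selection(top, sel_armB)
  if (!length(a) || !length(v) || !length(b))
    stop("hinge_angle_series: empty anchor selection")
  nf <- n_frames(traj)
  theta <- numeric(nf)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    pa <- center_of_mass(top, xyz, a) - center_of_mass(top, xyz, v)
    pb <- center_of_mass(top, xyz, b) - center_of_mass(top, xyz, v)
    na <- sqrt(sum(pa^2)); nb <- sqrt(sum(pb^2))
    theta[i] <- if (na < 1e-9 || nb < 1e-9) NA_real_ else
      acos(max(-1, min(1, sum(pa * pb) / (na * nb)))) * 180 / pi
  }
  if (anyNA(theta))
    warning("hinge_angle_series: coincident anchors in ",
            sum(is.na(theta)), " frame(s); angle undefined there")
  structure(list(times = traj$times, theta = theta), class = "angle_series")
}

#' Per-subunit membrane distance series
#'
#' Thin wrapper over [com_distance_series()] for per-subunit or per-residue
#' selections, e.g. the distance of each subunit's catalytic lysine from the
#' membrane COM.
#'
#' @inheritParams com_distance_series
#' @param subunit_sel subunit or residue selection
#' @export
subunit_distance_series <- function(traj, subunit_sel,
                                    membrane_sel = "lipid",
                                    metric = "z_component") {
  com_distance_series(traj, subunit_sel, membrane_sel, metric)
}

#' Geometric hydrogen-bond criterion
#'
#' Defaults follow the common geometric convention: donor-acceptor distance
#' at most 0.35 nm and hydrogen-donor-acceptor angle at most 30 degrees.
#'
#' @param d_max donor-acceptor maximum distance, nm
#' @param a_max H-D-A maximum angle, degrees
#' @export
hbond_criterion <- function(d_max = 0.35, a_max = 30) {
  if (d_max <= 0 || a_max <= 0) stop("hbond_criterion: cutoffs must be > 0")
  structure(list(d_max = d_max, a_max = a_max), class = "hbond_criterion")
}

#' Count hydrogen bonds per frame
#'
#' Counts (donor, hydrogen, acceptor) triples satisfying the geometric
#' criterion under the minimum-image convention.  Every donor must carry at
#' least one mapped hydrogen.
#'
#' @param traj a [trajectory()] over an atomistic topology
#' @param donor_set donor particle indices (or selection expression)
#' @param hydrogen_map named list: donor index (as character) -> hydrogen
#'   particle indices; see [infer_hydrogens()]
#' @param acceptor_set acceptor particle indices (or selection expression)
#' @param criterion an [hbond_criterion()]
#' @return integer vector of per-frame H-bond counts
#' @export
count_hbonds <- function(traj, donor_set, hydrogen_map, acceptor_set,
                         criterion = hbond_criterion()) {
  top <- traj$topology
  donors <- resolve_selection(top, donor_set)
  acceptors <- resolve_selection(top, acceptor_set)
  hs <- hydrogen_map[as.character(donors)]
  if (any(vapply(hs, function(h) is.null(h) || !length(h), logical(1))))
    stop("count_hbonds: donor without a mapped hydrogen")
  cosmax <- cos(criterion$a_max * pi / 180)
  nf <- n_frames(traj)
  out <- integer(nf)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    box <- traj$box[i, ]
    n <- 0L
    for (j in seq_along(donors)) {
      d <- donors[j]
      for (a in acceptors) {
        if (a == d) next
        v_da <- min_image_disp(xyz[a, ], xyz[d, ], box)
        if (sqrt(sum(v_da^2)) > criterion$d_max) next
        for (h in hs[[j]]) {
          v_dh <- min_image_disp(xyz[h, ], xyz[d, ], box)
          ca <- sum(v_da * v_dh) / sqrt(sum(v_da^2) * sum(v_dh^2))
          if (ca >= cosmax) { n <- n + 1L; break }
        }
      }
    }
    out[i] <- n
  }
  out
}

#' Map donors to their bonded hydrogens by proximity
#'
#' Assigns every particle whose name starts with `H` lying within `d_bond`
#' of a donor in the given frame to that donor.
#'
#' @param top a [topology()]
#' @param fr a [frame()]
#' @param donors donor particle indices
#' @param d_bond covalent-bond distance cutoff, nm
#' @return named list: donor index (character) -> hydrogen indices
#' @export
infer_hydrogens <- function(top, fr, donors, d_bond = 0.12) {
  hyd <- which(grepl("^H", top$particles$name))
  out <- stats::setNames(vector("list", length(donors)),
                         as.character(donors))
  if (!length(hyd)) return(out)
  d2 <- min_image_dist2_matrix(fr$coords[donors, , drop = FALSE],
                               fr$coords[hyd, , drop = FALSE], fr$box)
  for (j in seq_along(donors))
    out[[j]] <- hyd[d2[j, ] <= d_bond^2]
  out
}

#' Centred moving average with shrinking edge windows
#'
#' @param values numeric series
#' @param window window width in ns
#' @param dt frame spacing in ns (so the window spans `window / dt` frames)
#' @return numeric series of the same length
#' @export
moving_average <- function(values, window, dt = 1) {
  if (window <= 0) stop("moving_average: window must be > 0")
  half <- max(0L, floor(window / dt / 2))
  n <- length(values)
  vapply(seq_len(n), function(i) {
    mean(values[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed (Kabsch) on the first frame, the time-average
#' structure is computed, frames are re-superposed onto it (or onto frame 1
#' with `reference = "frame1"`), and
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` is reported per residue of the
#' selection (conventionally one C-alpha or backbone particle per residue).
#'
#' @param traj a [trajectory()] with at least 2 frames
#' @param selection particle selection (default `"name CA"`)
#' @param reference `"average"` or `"frame1"`
#' @return data frame with `residue` and `rmsf` (nm)
#' @export
rmsf <- function(traj, selection = "name CA",
                 reference = c("average", "frame1")) {
  reference <- match.arg(reference)
  if (n_frames(traj) < 2) stop("rmsf: need >= 2 frames")
  sel <- resolve_selection(traj$topology, selection)
  if (!length(sel)) stop("rmsf: empty selection (no C-alpha particles?)")
  nf <- n_frames(traj)
  w <- traj$topology$particles$mass[sel]
  aligned <- array(0, dim = c(length(sel), 3, nf))
  ref <- traj$coords[sel, , 1]
  for (i in seq_len(nf))
    aligned[, , i] <- superpose_onto(traj$coords[sel, , i], ref, w)
  if (reference == "average") {
    avg <- apply(aligned, c(1, 2), mean)
    for (i in seq_len(nf))
      aligned[, , i] <- superpose_onto(aligned[, , i], avg, w)
    avg <- apply(aligned, c(1, 2), mean)
  } else {
    avg <- apply(aligned, c(1, 2), mean)
  }
  disp2 <- vapply(seq_len(nf), function(i)
    rowSums((aligned[, , i] - avg)^2), numeric(length(sel)))
  per_particle <- sqrt(rowMeans(matrix(disp2, nrow = length(sel))))
  res <- traj$topology$particles$resid[sel]
  agg <- tapply(per_particle, res, mean)
  data.frame(residue = as.integer(names(agg)), rmsf = as.numeric(agg))
}

# rigid superposition of X onto ref (weighted Kabsch + COM match)
superpose_onto <- function(X, ref, w = NULL) {
  wn <- if (is.null(w)) rep(1, nrow(X)) else w / sum(w)
  wn <- wn / sum(wn)
  comx <- colSums(X * wn); comr <- colSums(ref * wn)
  R <- kabsch(X, ref, w)
  sweep(sweep(X, 2, comx) %*% t(R), 2, comr, "+")
}
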