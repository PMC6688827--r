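#' Pick a productively bound reference frame
#'
#' Default policy: across all trajectories, take the frame maximising the
#' number of catalytic-site residues (by default the conserved PIP-binding
#' motif, residues 180-184) in contact with the lipid target — i.e. a frame
#' in which the catalytic site faces the bilayer headgroups.  A user-supplied
#' reference coordinate matrix overrides the search.
#'
#' @param trajs list of [trajectory()] objects
#' @param protein_sel selection defining the reference coordinate set
#' @param site_residues catalytic-site residues used to score frames
#' @param lipid_target_sel,cutoff,mode contact configuration, as in
#'   [residue_contact_profile()]
#' @param reference optional user-supplied N x 3 matrix (provenance "user")
#' @return list with `coords` (reference coordinates for `protein_sel`),
#'   `provenance`, and for searched references `traj_index`, `frame_index`
#' @export
pick_reference <- function(trajs, protein_sel = "protein",
                           site_residues = 180:184,
                           lipid_target_sel = "species PI4P and headgroup",
                           cutoff = 0.7, mode = "min_particle",
                           reference = NULL) {
  if (!is.null(reference))
    return(list(coords = as.matrix(reference), provenance = "user"))
  stopifnot(length(trajs) >= 1)
  best <- list(score = 0L)
  for (ti in seq_along(trajs)) {
    traj <- trajs[[ti]]
    occ <- contact_matrix(traj, site_residues, lipid_target_sel, cutoff, mode)
    score <- colSums(occ)
    if (max(score) > best$score) {
      fi <- which.max(score)
      sel <- resolve_selection(traj$topology, protein_sel)
      best <- list(score = max(score), traj_index = ti, frame_index = fi,
                   coords = traj$coords[sel, , fi])
    }
  }
  if (best$score == 0L)
    stop("pick_reference: no frame with catalytic-site contacts; ",
         "supply a reference structure explicitly")
  list(coords = best$coords, provenance = "search",
       traj_index = best$traj_index, frame_index = best$frame_index)
}

#' Per-frame orientation (Rzz) series against a reference
#'
#' @param traj a [trajectory()]
#' @param protein_sel selection matched against the reference coordinates
#' @param reference N x 3 matrix, or the result of [pick_reference()]
#' @param weights `"mass"` (default) or `"uniform"` Kabsch weighting
#' @return object of class `orientation_series`: list of `times`, `rzz`
#' @export
orientation_series <- function(traj, protein_sel = "protein", reference,
                               weights = c("mass", "uniform")) {
  weights <- match.arg(weights)
  if (is.list(reference) && !is.null(reference$coords))
    reference <- reference$coords
  reference <- as.matrix(reference)
  sel <- resolve_selection(traj$topology, protein_sel)
  if (length(sel) != nrow(reference))
    stop("orientation_series: selection size (", length(sel),
         ") does not match reference (", nrow(reference), ")")
  w <- if (weights == "mass") traj$topology$particles$mass[sel] else NULL
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i)
    rzz(traj$coords[sel, , i], reference, w), numeric(1))
  structure(list(times = traj$times, rzz = vals, weights = weights),
            class = "orientation_series")
}

#' Pooled distance-orientation density map
#'
#' Pools all replicate frames into one 2D histogram over (membrane distance,
#' Rzz) and normalises it to a probability (sums to 1).
#'
#' @param distance_list list of `distance_series` (z-component metric)
#' @param rzz_list matching list of `orientation_series`
#' @param n_bins_d,n_bins_r bin counts
#' @param d_range,r_range axis ranges; default spans the observed values
#' @return object of class `density_map`: list with `d_edges`, `r_edges`,
#'   `prob` (distance-bin x rzz-bin matrix), `n_frames`
#' @export
distance_orientation_map <- function(distance_list, rzz_list,
                                     n_bins_d = 50, n_bins_r = 50,
                                     d_range = NULL, r_range = NULL) {
  if (!length(distance_list)) stop("distance_orientation_map: empty input")
  stopifnot(length(distance_list) == length(rzz_list))
  d <- unlist(lapply(distance_list, `[[`, "values"))
  r <- unlist(lapply(rzz_list, `[[`, "rzz"))
  for (i in seq_along(distance_list))
    if (length(distance_list[[i]]$values) != length(rzz_list[[i]]$rzz))
      stop("distance_orientation_map: pair ", i, " is not time-aligned")
  d_range <- d_range %||% range(d)
  r_range <- r_range %||% range(r)
  if (diff(d_range) == 0) d_range <- d_range + c(-0.5, 0.5)
  if (diff(r_range) == 0) r_range <- r_range + c(-0.05, 0.05)
  d_edges <- seq(d_range[1], d_range[2], length.out = n_bins_d + 1)
  r_edges <- seq(r_range[1], r_range[2], length.out = n_bins_r + 1)
  di <- pmin(pmax(findInterval(d, d_edges, rightmost.closed = TRUE), 1), n_bins_d)
  ri <- pmin(pmax(findInterval(r, r_edges, rightmost.closed = TRUE), 1), n_bins_r)
  counts <- matrix(0, n_bins_d, n_bins_r)
  for (k in seq_along(d)) counts[di[k], ri[k]] <- counts[di[k], ri[k]] + 1
  structure(list(d_edges = d_edges, r_edges = r_edges,
                 prob = counts / sum(counts), n_frames = length(d)),
            class = "density_map")
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Detect binding modes as peaks of the density map
#'
#' Smooths the map with a Gaussian kernel (default sigma of one bin,
#' renormalised at the edges), finds local maxima of the smoothed density,
#' and keeps the top `k` under a greedy non-adjacency rule (peaks at least 2
#' bins apart, Chebyshev).  Each mode's mass is the probability of the bins
#' nearer (in bin units) to that peak than to any other kept peak.  Ties in
#' density are broken toward the lowest distance bin, then lowest Rzz bin.
#'
#' @param map a `density_map`
#' @param k number of modes sought (>= 1)
#' @param smooth_sigma Gaussian smoothing sigma, in bins
#' @param min_separation minimum peak separation, bins
#' @return list of modes, each with `d` (peak distance, nm), `rzz`, `mass`,
#'   `d_bin`, `r_bin`, `label`; fewer than `k` maxima yields a warning and a
#'   shorter list
#' @export
find_modes <- function(map, k = 2, smooth_sigma = 1, min_separation = 2) {
  stopifnot(inherits(map, "density_map"), k >= 1)
  sm <- gaussian_smooth_2d(map$prob, smooth_sigma)
  sm <- signif(sm, 10)  # stabilise ties against last-ulp smoothing noise
  nd <- nrow(sm); nr <- ncol(sm)
  # local maxima over the 8-neighbourhood (edges padded with -Inf)
  pad <- matrix(-Inf, nd + 2, nr + 2)
  pad[2:(nd + 1), 2:(nr + 1)] <- sm
  is_max <- matrix(TRUE, nd, nr)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    is_max <- is_max & (sm >= pad[2:(nd + 1) + dx, 2:(nr + 1) + dy])
  }
  cand <- which(is_max & sm > 0, arr.ind = TRUE)
  if (!nrow(cand)) {
    warning("find_modes: no local maxima found")
    return(list())
  }
  dens <- sm[cand]
  o <- order(-dens, cand[, 1], cand[, 2])  # tie-break: low d bin, low r bin
  cand <- cand[o, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == k) break
    if (!nrow(kept) ||
        all(pmax(abs(kept[, 1] - cand[i, 1]),
                 abs(kept[, 2] - cand[i, 2])) >= min_separation))
      kept <- rbind(kept, cand[i, ])
  }
  if (nrow(kept) < k)
    warning("find_modes: only ", nrow(kept), " separated maxima found (k = ",
            k, ")")
  # nearest-peak mass assignment
  dc <- bin_centers(map$d_edges); rc <- bin_centers(map$r_edges)
  grid <- expand.grid(d_bin = seq_len(nd), r_bin = seq_len(nr))
  dist2 <- sapply(seq_len(nrow(kept)), function(j)
    (grid$d_bin - kept[j, 1])^2 + (grid$r_bin - kept[j, 2])^2)
  owner <- if (nrow(kept) == 1) rep(1L, nrow(grid)) else
    max.col(-as.matrix(dist2), ties.method = "first")
  masses <- vapply(seq_len(nrow(kept)), function(j)
    sum(map$prob[cbind(grid$d_bin, grid$r_bin)][owner == j]), numeric(1))
  lapply(seq_len(nrow(kept)), function(j) {
    list(d = dc[kept[j, 1]], rzz = rc[kept[j, 2]], mass = masses[j],
         d_bin = as.integer(kept[j, 1]), r_bin = as.integer(kept[j, 2]),
         label = paste0("mode", j))
  })
}

gaussian_smooth_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-half:half, sd = sigma)
  k2 <- outer(g, g)
  nd <- nrow(m); nr <- ncol(m)
  out <- matrix(0, nd, nr)
  norm <- matrix(0, nd, nr)
  for (dx in -half:half) for (dy in -half:half) {
    w <- k2[dx + half + 1, dy + half + 1]
    xs <- max(1, 1 - dx):min(nd, nd - dx)
    ys <- max(1, 1 - dy):min(nr, nr - dy)
    out[xs, ys] <- out[xs, ys] + w * m[xs + dx, ys + dy]
    norm[xs, ys] <- norm[xs, ys] + w
  }
  out / norm
}

#' Write a density map as long-format CSV
#'
#' Columns `d_bin`, `rzz_bin` (bin centres) and `probability`.
#'
#' @param map a `density_map`
#' @param path output path
#' @export
write_density_map <- function(map, path) {
  dc <- bin_centers(map$d_edges); rc <- bin_centers(map$r_edges)
  out <- data.frame(d_bin = rep(dc, times = length(rc)),
                    rzz_bin = rep(rc, each = length(dc)),
                    probability = as.numeric(map$prob))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Render a density map heatmap
#' @param map a `density_map`
#' @param ... passed to [graphics::image()]
#' @export
plot_density_map <- function(map, ...) {
  graphics::image(bin_centers(map$d_edges), bin_centers(map$r_edges),
                  map$prob, xlab = "membrane distance (nm)",
                  ylab = expression(R[zz]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(map)
}
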