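#' Protein-membrane COM distance series
#'
#' Per-frame separation of the centres of mass of two selections, with the
#' minimum-image convention applied componentwise.  `metric = "z_component"`
#' returns the absolute z separation (both leaflet approaches map
#' identically); `"euclidean3d"` the full 3D distance.
#'
#' @param traj a [trajectory()]
#' @param protein_sel,membrane_sel selection expressions (see
#'   [select_particles()]) or integer particle index vectors
#' @param metric `"z_component"` or `"euclidean3d"`
#' @return object of class `distance_series`: list with `times` (ns),
#'   `values` (nm), `metric`, `selections`
#' @export
com_distance_series <- function(traj, protein_sel = "protein",
                                membrane_sel = "lipid",
                                metric = c("z_component", "euclidean3d")) {
  metric <- match.arg(metric)
  a <- resolve_selection(traj$topology, protein_sel)
  b <- resolve_selection(traj$topology, membrane_sel)
  if (!length(a) || !length(b))
    stop("com_distance_series: empty selection")
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    d <- min_image_disp(center_of_mass(traj$topology, xyz, a),
                        center_of_mass(traj$topology, xyz, b), traj$box[i, ])
    vals[i] <- if (metric == "z_component") abs(d[3]) else sqrt(sum(d^2))
  }
  structure(list(times = traj$times, values = vals, metric = metric,
                 selections = list(protein = protein_sel,
                                   membrane = membrane_sel)),
            class = "distance_series")
}

resolve_selection <- function(top, sel) {
  if (is.character(sel)) select_particles(top, sel) else as.integer(sel)
}

distance_series <- function(times, values, metric = "z_component",
                            selections = list()) {
  stopifnot(length(times) == length(values))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 metric = metric, selections = selections),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat("<distance_series> ", length(x$times), " points, metric ", x$metric,
      ", range ", round(min(x$values), 3), "-", round(max(x$values), 3),
      " nm\n", sep = "")
  invisible(x)
}

#' Pointwise ensemble mean of distance series
#'
#' All series must share one time grid (the estimator is a per-time mean over
#' replicates, as used for N = 5 or 25 replicate ensembles); pass
#' `resample = TRUE` to linearly interpolate onto the first series' grid
#' instead.
#'
#' @param series_list list of `distance_series`
#' @param resample interpolate onto a common grid instead of erroring on
#'   mismatched grids
#' @return a `distance_series` with an `sd` element (per-time s.d. across
#'   replicates, `NA` for a single series)
#' @export
ensemble_mean <- function(series_list, resample = FALSE) {
  stopifnot(length(series_list) >= 1)
  t0 <- series_list[[1]]$times
  vals <- lapply(series_list, function(s) {
    if (isTRUE(all.equal(s$times, t0))) return(s$values)
    if (!resample)
      stop("ensemble_mean: time grids differ (set resample = TRUE)")
    stats::approx(s$times, s$values, xout = t0, rule = 2)$y
  })
  m <- matrix(unlist(vals), nrow = length(t0))
  out <- distance_series(t0, rowMeans(m), series_list[[1]]$metric,
                         list(ensemble_of = length(series_list)))
  out$sd <- if (ncol(m) > 1) apply(m, 1, stats::sd) else rep(NA_real_, length(t0))
  out
}

#' Exponential fit to a binding curve
#'
#' Least-squares fit of `d(t) = d_inf + (d0 - d_inf) exp(-t / tau)` with
#' `tau` bounded positive (Levenberg-Marquardt).  Start values: `d0` = first
#' point, `d_inf` = last point, `tau` = half the time span.
#'
#' @param series a `distance_series` (>= 4 points, non-constant)
#' @return object of class `binding_fit`: list with `d0`, `d_inf`, `tau`
#'   (ns), `residual_rms` (nm), `converged`; on failure `converged = FALSE`
#'   with a `diagnostics` message and `NA` parameters (no exception)
#' @export
fit_binding_curve <- function(series) {
  t <- series$times; d <- series$values
  if (length(t) < 4) stop("fit_binding_curve: need >= 4 points")
  if (max(d) - min(d) < .Machine$double.eps^0.5 * max(abs(d), 1))
    stop("fit_binding_curve: series is constant")
  span <- t[length(t)] - t[1]
  resid_fn <- function(par)
    par[["d_inf"]] + (par[["d0"]] - par[["d_inf"]]) *
      exp(-t / max(par[["tau"]], 1e-12)) - d
  run_lm <- function(tau0) {
    tryCatch(
      minpack.lm::nls.lm(par = c(d0 = d[1], d_inf = d[length(d)], tau = tau0),
                         fn = resid_fn, lower = c(-Inf, -Inf, 1e-12),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
  }
  lm_ok <- function(f) !inherits(f, "error") && f$info %in% 1:4
  # primary start: tau = half the time span.  If that collapses onto the
  # tau lower bound (a degenerate constant-fit minimum), restart from the
  # observed 1/e decay time.
  fit <- run_lm(span / 2)
  if (!lm_ok(fit) || fit$par[["tau"]] < 1e-9) {
    target <- d[length(d)] + (d[1] - d[length(d)]) / exp(1)
    idx <- which(d <= target)
    tau_b <- if (length(idx)) max(t[idx[1]] - t[1], span / 100) else span / 10
    fit2 <- run_lm(tau_b)
    better <- lm_ok(fit2) && fit2$par[["tau"]] >= 1e-9 &&
      (!lm_ok(fit) || sum(fit2$fvec^2) <= sum(fit$fvec^2))
    if (better) fit <- fit2
  }
  if (!lm_ok(fit)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    return(structure(list(d0 = NA_real_, d_inf = NA_real_, tau = NA_real_,
                          residual_rms = NA_real_, converged = FALSE,
                          diagnostics = msg),
                     class = "binding_fit"))
  }
  cf <- fit$par
  structure(list(d0 = unname(cf[["d0"]]), d_inf = unname(cf[["d_inf"]]),
                 tau = unname(cf[["tau"]]),
                 residual_rms = sqrt(mean(fit$fvec^2)),
                 converged = TRUE, diagnostics = ""),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<binding_fit> d0 = %.3f nm, d_inf = %.3f nm, tau = %.2f ns, rms = %.4f nm\n",
                x$d0, x$d_inf, x$tau, x$residual_rms))
  else cat("<binding_fit> not converged:", x$diagnostics, "\n")
  invisible(x)
}

# ---- contacts --------------------------------------------------------------

# per-frame residue x lipid contact matrix machinery shared by the profile
# and time-series operations.  Returns residue x frame matrix of either 0/1
# (contact with any target lipid) or the number of target lipids in contact.
contact_matrix <- function(traj, protein_residues, lipid_target_sel, cutoff,
                           mode = c("min_particle", "com"),
                           per_lipid_count = FALSE) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("contacts: cutoff must be > 0")
  top <- traj$topology
  tgt <- resolve_selection(top, lipid_target_sel)
  prot_rows <- which(top$particles$species == "protein" &
                     top$particles$resid %in% protein_residues)
  res_of_row <- top$particles$resid[prot_rows]
  residues <- protein_residues
  nf <- n_frames(traj)
  occ <- matrix(0L, length(residues), nf,
                dimnames = list(residue = residues, NULL))
  if (!length(tgt)) {
    warning("contacts: empty lipid target selection; all-zero result")
    return(occ)
  }
  lipid_res <- top$particles$resid[tgt]
  cut2 <- cutoff^2
  masses <- top$particles$mass
  res_f <- factor(res_of_row, levels = residues)
  lip_f <- factor(lipid_res)
  keep <- !is.na(res_f)
  prot_rows <- prot_rows[keep]
  res_f <- droplevels(res_f[keep])
  # rowsum() drops absent groups; map its rows back onto requested residues
  row_idx <- match(levels(res_f), as.character(residues))
  mres <- masses[prot_rows]
  mlip <- masses[tgt]
  mres_tot <- as.numeric(rowsum(mres, res_f))
  mlip_tot <- as.numeric(rowsum(mlip, lip_f))
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    box <- traj$box[i, ]
    if (mode == "min_particle") {
      d2 <- min_image_dist2_matrix(xyz[prot_rows, , drop = FALSE],
                                   xyz[tgt, , drop = FALSE], box)
      hit <- d2 < cut2  # strict: a pair at exactly the cutoff is no contact
      if (per_lipid_count) {
        by_res <- rowsum(hit + 0L, res_f)             # residue x target part.
        by_lip <- t(rowsum(t(by_res), lip_f))         # residue x lipid
        occ[row_idx, i] <- rowSums(by_lip > 0)
      } else {
        occ[row_idx, i] <- as.integer(rowsum(rowSums(hit), res_f)[, 1] > 0)
      }
    } else {
      rcom <- rowsum(xyz[prot_rows, , drop = FALSE] * mres, res_f) / mres_tot
      lcom <- rowsum(xyz[tgt, , drop = FALSE] * mlip, lip_f) / mlip_tot
      d2 <- min_image_dist2_matrix(rcom, lcom, box)
      hit <- d2 < cut2
      occ[row_idx, i] <- if (per_lipid_count) rowSums(hit) else
        as.integer(rowSums(hit) > 0)
    }
  }
  occ
}

#' Residue-lipid contact profile
#'
#' Counts, for every protein residue, the frames in which it contacts the
#' lipid target.  `mode = "min_particle"` (coarse-grained convention,
#' 0.7 nm): a residue is in contact when the minimum distance over all
#' residue-particle / target-particle pairs is strictly below the cutoff.
#' `mode = "com"` (atomistic convention, 0.35 nm): the residue COM to
#' per-lipid headgroup COM distance is below the cutoff.  Raw counts are
#' normalised to the residue with the largest number of contacts.
#'
#' @param traj a [trajectory()]
#' @param protein_residues residue indices to profile (default: all protein
#'   residues)
#' @param lipid_target_sel target selection (default: PI4P headgroups)
#' @param cutoff contact cutoff, nm
#' @param mode contact definition (see above)
#' @param per_lipid_count count contacting lipids per frame instead of 0/1
#' @return object of class `contact_profile`: data frame with `residue`,
#'   `raw`, `normalized`, plus attributes `cutoff`, `mode`, `all_zero`
#' @export
residue_contact_profile <- function(traj, protein_residues = NULL,
                                    lipid_target_sel = "species PI4P and headgroup",
                                    cutoff = 0.7,
                                    mode = c("min_particle", "com"),
                                    per_lipid_count = FALSE) {
  mode <- match.arg(mode)
  protein_residues <- protein_residues %||%
    sort(unique(traj$topology$particles$resid[
      traj$topology$particles$species == "protein"]))
  occ <- contact_matrix(traj, protein_residues, lipid_target_sel, cutoff,
                        mode, per_lipid_count)
  raw <- rowSums(occ)
  prof <- data.frame(residue = protein_residues, raw = as.integer(raw),
                     normalized = 0)
  prof <- normalize_profile(structure(prof, cutoff = cutoff, mode = mode,
                                      class = c("contact_profile",
                                                "data.frame")))
  prof
}

#' Normalise a contact profile to its maximum residue
#'
#' `normalized_i = raw_i / max_j raw_j`; an all-zero profile stays all-zero
#' and is flagged via the `all_zero` attribute.
#'
#' @param profile a `contact_profile`
#' @return the profile with its `normalized` column filled in
#' @export
normalize_profile <- function(profile) {
  mx <- max(profile$raw)
  profile$normalized <- if (mx > 0) profile$raw / mx else 0
  attr(profile, "all_zero") <- mx == 0
  profile
}

#' Residue-by-frame contact occupancy
#'
#' Same contact definitions as [residue_contact_profile()]; row sums
#' reproduce the profile's raw counts exactly.
#'
#' @inheritParams residue_contact_profile
#' @return object of class `contact_series`: residue x frame integer matrix
#'   with attributes `times`, `cutoff`, `mode`
#' @export
contact_timeseries <- function(traj, protein_residues = NULL,
                               lipid_target_sel = "species PI4P and headgroup",
                               cutoff = 0.7, mode = c("min_particle", "com"),
                               per_lipid_count = FALSE) {
  mode <- match.arg(mode)
  protein_residues <- protein_residues %||%
    sort(unique(traj$topology$particles$resid[
      traj$topology$particles$species == "protein"]))
  occ <- contact_matrix(traj, protein_residues, lipid_target_sel, cutoff,
                        mode, per_lipid_count)
  structure(occ, times = traj$times, cutoff = cutoff, mode = mode,
            class = c("contact_series", class(occ)))
}

#' Count lipids proximal to a site
#'
#' Number of target lipids whose headgroup COM lies within `radius`
#' (minimum image) of the site selection's COM, per frame — e.g. substrate
#' lipids within 3.5 nm of an active site.
#'
#' @param traj a [trajectory()]
#' @param site_sel site selection (expression or indices); must be non-empty
#' @param lipid_sel lipid selection; lipids are grouped by residue and
#'   their headgroup particles define the lipid position
#' @param radius nm
#' @return integer vector, one count per frame
#' @export
count_proximal_lipids <- function(traj, site_sel,
                                  lipid_sel = "species PI4P and headgroup",
                                  radius = 3.5) {
  if (radius <= 0) stop("count_proximal_lipids: radius must be > 0")
  top <- traj$topology
  site <- resolve_selection(top, site_sel)
  if (!length(site)) stop("count_proximal_lipids: empty site selection")
  tgt <- resolve_selection(top, lipid_sel)
  lip_groups <- split(tgt, top$particles$resid[tgt])
  masses <- top$particles$mass
  nf <- n_frames(traj)
  out <- integer(nf)
  if (!length(tgt)) return(out)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    scom <- center_of_mass(top, xyz, site)
    lcom <- t(vapply(lip_groups, function(rows) {
      m <- masses[rows]
      colSums(xyz[rows, , drop = FALSE] * m) / sum(m)
    }, numeric(3)))
    d2 <- min_image_dist2_matrix(matrix(scom, 1), lcom, traj$box[i, ])
    out[i] <- sum(d2 <= radius^2)
  }
  out
}

#' Write a contact profile as CSV
#'
#' Adds a `pdb_residue` column via the residue map where the simulation
#' residue is mappable (`NA` elsewhere).
#'
#' @param profile a `contact_profile`
#' @param path output path
#' @param map optional [residue_map()]
#' @export
write_contact_profile <- function(profile, path, map = default_residue_map()) {
  pdb <- vapply(profile$residue, function(r) {
    tryCatch(map_residue(map, r), error = function(e) NA_integer_)
  }, integer(1))
  out <- data.frame(residue = profile$residue, pdb_residue = pdb,
                    raw = profile$raw, normalized = profile$normalized)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
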