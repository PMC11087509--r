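#' Resolve an atom selection against a topology
#'
#' Selections are used both for rigid-body fitting (e.g. the phosphate /
#' scaffold atoms) and for analysis subsets (e.g. peptide heavy atoms).
#' All criteria given are combined with AND.
#'
#' @param model a [structure_model()] (the topology).
#' @param atom_name optional character vector of atom names to keep.
#' @param element optional character vector of element symbols to keep.
#' @param residue_range optional `c(lo, hi)` of residue indices to keep.
#' @param heavy_only if `TRUE`, drop hydrogens.
#' @return strictly increasing integer vector of atom indices.
#' @export
select_atoms <- function(model, atom_name = NULL, element = NULL,
                         residue_range = NULL, heavy_only = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  keep <- rep(TRUE, nrow(model$atoms))
  if (!is.null(atom_name))
    keep <- keep & model$atoms$atom_name %in% atom_name
  if (!is.null(element))
    keep <- keep & toupper(model$atoms$element) %in% toupper(element)
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    keep <- keep & model$atoms$residue_index >= residue_range[1] &
      model$atoms$residue_index <= residue_range[2]
  }
  if (heavy_only) keep <- keep & is_heavy(model)
  which(keep)
}

#' Rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' selected atoms of a mobile and a reference coordinate set. Reflections are
#' rejected by sign-correcting the singular vector of the smallest singular
#' value, so the returned rotation always has determinant +1.
#'
#' @param mobile,reference numeric matrices `n x 3` with matching atom order.
#' @param selection integer vector of row indices used for the fit (default
#'   all rows); must resolve to at least 3 non-collinear atoms.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3), and
#'   `rmsd` (Angstrom, computed over the selection after transforming).
#'   Applying the transform maps `mobile` onto `reference`:
#'   `mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L)
    stop("superposition requires at least 3 selected atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of the centered selection must be >= 2
  if (sum(svd(A0)$d > max(dim(A0)) * .Machine$double.eps * max(svd(A0)$d, 1)) < 2L)
    stop("degenerate (collinear) selection: rotation is not determined")
  H <- crossprod(A0, B0)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- cb - as.numeric(R %*% ca)
  fitted <- A %*% t(R) + matrix(translation, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz numeric matrix `n x 3`.
#' @param transform a list with `rotation` and `translation` as returned by
#'   [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- as.matrix(xyz)
  xyz %*% t(transform$rotation) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Invert a rigid transform
#' @param transform list with `rotation`, `translation`.
#' @return the inverse transform.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  list(rotation = Rt, translation = -as.numeric(Rt %*% transform$translation))
}

#' Superpose every frame of an ensemble onto a reference
#'
#' Applies [kabsch_superpose()] frame by frame using a fitting selection
#' (e.g. the rigid scaffold / phosphate atoms) and replaces the coordinates
#' with the fitted ones, mimicking the standard trajectory preprocessing
#' before any density or mode analysis.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param reference numeric `n x 3` matrix (or [structure_model()]) to fit to.
#' @param selection integer atom indices used for fitting.
#' @return the ensemble with fitted coordinates; per-frame RMSDs in
#'   `attr(, "fit_rmsd")`.
#' @export
fit_ensemble <- function(ensemble, reference, selection) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (inherits(reference, "structure_model")) reference <- coords(reference)
  reference <- as.matrix(reference)
  n_atoms <- dim(ensemble$coords)[1]
  # the reference may be given either full-size or already restricted to the
  # fitting selection (e.g. a scaffold-only model)
  ref_sel <- if (nrow(reference) == n_atoms) reference[selection, , drop = FALSE]
             else if (nrow(reference) == length(selection)) reference
             else stop("reference must have n_atoms or length(selection) rows")
  rmsds <- numeric(n_frames(ensemble))
  for (i in seq_len(n_frames(ensemble))) {
    tr <- kabsch_superpose(ensemble$coords[selection, , i], ref_sel)
    ensemble$coords[, , i] <- apply_transform(ensemble$coords[, , i], tr)
    rmsds[i] <- tr$rmsd
  }
  attr(ensemble, "fit_rmsd") <- rmsds
  ensemble
}

#' Frame-pool extraction rule
#'
#' Selects, from a vector of recorded frame times, those frames lying on the
#' extraction lattice: discard everything before `discard_ns`, then keep the
#' frames nearest to `discard_ns + k * interval_ns` (k = 0, 1, ...) up to and
#' including the last recorded time. Snapping tolerance is half the recording
#' timestep, so discrete recording grids (e.g. 5 ps) match robustly.
#'
#' @param times_ns numeric vector of recorded frame times (ns), increasing.
#' @param discard_ns length of the initial segment to discard (default 500).
#' @param interval_ns extraction interval (default 250), > 0.
#' @param timestep_ns recording timestep used for the snapping tolerance;
#'   default is the median spacing of `times_ns`.
#' @return integer vector of selected frame indices (possibly empty, with a
#'   warning, when the trajectory is shorter than `discard_ns`).
#' @export
frame_pool_indices <- function(times_ns, discard_ns = 500, interval_ns = 250,
                               timestep_ns = NULL) {
  stopifnot(interval_ns > 0, discard_ns >= 0)
  if (!length(times_ns)) return(integer(0))
  if (is.null(timestep_ns))
    timestep_ns <- if (length(times_ns) > 1L) stats::median(diff(times_ns)) else 0
  t_last <- times_ns[length(times_ns)]
  if (t_last < discard_ns - timestep_ns / 2) {
    warning("trajectory shorter than discard window; contributes no frames")
    return(integer(0))
  }
  n_pts <- floor((t_last + timestep_ns / 2 - discard_ns) / interval_ns)
  lattice <- discard_ns + (0:max(n_pts, 0)) * interval_ns
  idx <- vapply(lattice, function(tt) {
    j <- which.min(abs(times_ns - tt))
    if (abs(times_ns[j] - tt) <= timestep_ns / 2 + 1e-9) j else NA_integer_
  }, integer(1))
  unique(idx[!is.na(idx)])
}

#' Build the structure pool from a set of trajectories
#'
#' Applies [frame_pool_indices()] to every ensemble and concatenates the
#' selected frames in trajectory order, then time order. With the defaults
#' (discard 500 ns, interval 250 ns) and 15 trajectories of 2000 ns
#' production span this yields a pool of 105 structures.
#'
#' @param ensembles list of [trajectory_ensemble()] objects.
#' @param discard_ns,interval_ns,timestep_ns see [frame_pool_indices()].
#' @return A data.frame manifest with columns `ensemble` (list index),
#'   `origin_conformation`, `replica_id`, `frame_index`, `time_ns`; the
#'   frame coordinate matrices are attached as the list attribute
#'   `attr(, "frames")`, in manifest order.
#' @export
build_structure_pool <- function(ensembles, discard_ns = 500,
                                 interval_ns = 250, timestep_ns = NULL) {
  stopifnot(length(ensembles) >= 1L)
  rows <- list(); frames <- list()
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    stopifnot(inherits(ens, "trajectory_ensemble"))
    idx <- frame_pool_indices(ens$times_ns, discard_ns, interval_ns, timestep_ns)
    for (i in idx) {
      rows[[length(rows) + 1L]] <- data.frame(
        ensemble = e, origin_conformation = ens$origin_conformation,
        replica_id = ens$replica_id, frame_index = i,
        time_ns = ens$times_ns[i])
      frames[[length(frames) + 1L]] <- frame_coords(ens, i)
    }
  }
  if (!length(rows)) stop("structure pool is empty")
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  attr(manifest, "frames") <- frames
  manifest
}
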