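#' Principal conformational modes of an ensemble
#'
#' Computes the covariance matrix of mean-centered Cartesian coordinates of
#' the selected atoms (mass-unweighted by default) over frames subsampled at
#' `sample_interval_ns`, and eigendecomposes it. Frames must already be
#' rigid-body fitted to a common reference (see [fit_ensemble()]).
#' Eigenvector signs are fixed so that each vector's largest-magnitude
#' component is positive, making projections deterministic across runs.
#'
#' @param ensembles list of [trajectory_ensemble()] objects (pooled).
#' @param selection integer atom indices entering the covariance (e.g.
#'   peptide heavy atoms).
#' @param sample_interval_ns frame subsampling interval for the covariance
#'   estimate (default 1 ns); projection, by contrast, is done at full
#'   recording resolution.
#' @param mass_weighted if `TRUE`, coordinates are scaled by `sqrt(mass)`
#'   using integer atomic numbers as a mass proxy.
#' @return list of class `mode_basis` with `mean_coordinates` (n_sel x 3),
#'   `eigenvectors` (3*n_sel x n_modes, orthonormal columns), `eigenvalues`
#'   (A^2, non-increasing), `variance_fractions`, `selection`, `n_frames`.
#' @export
pca_modes <- function(ensembles, selection, sample_interval_ns = 1.0,
                      mass_weighted = FALSE) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1L, length(selection) >= 1L)
  rows <- list()
  for (ens in ensembles) {
    idx <- frame_pool_indices(ens$times_ns, discard_ns = 0,
                              interval_ns = sample_interval_ns)
    for (i in idx)
      rows[[length(rows) + 1L]] <-
        as.numeric(t(ens$coords[selection, , i]))  # x1 y1 z1 x2 ...
  }
  if (length(rows) < 2L)
    stop("pca_modes requires at least 2 sampled frames")
  M <- do.call(rbind, rows)
  if (mass_weighted) {
    w <- sqrt(rep(atomic_number(
      ensembles[[1]]$topology$atoms$element[selection]), each = 3L))
    M <- sweep(M, 2, w, `*`)
  }
  mu <- colMeans(M)
  C <- stats::cov(M)               # 1/(n-1) normalization
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  V <- eig$vectors
  # deterministic sign: largest-|component| positive
  for (j in seq_len(ncol(V))) {
    jmax <- which.max(abs(V[, j]))
    if (V[jmax, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(
    mean_coordinates = matrix(mu, ncol = 3, byrow = TRUE),
    mean_flat = mu,
    eigenvectors = V,
    eigenvalues = lambda,
    variance_fractions = if (sum(lambda) > 0) lambda / sum(lambda) else lambda,
    selection = selection,
    mass_weighted = mass_weighted,
    n_frames = nrow(M)), class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("mode_basis: %d atoms, %d frames; leading variance fractions: %s\n",
              length(x$selection), x$n_frames,
              paste(sprintf("%.3f", x$variance_fractions[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

.flatten_frames <- function(ens, selection) {
  nf <- n_frames(ens)
  out <- matrix(0, nf, 3L * length(selection))
  for (i in seq_len(nf)) out[i, ] <- as.numeric(t(ens$coords[selection, , i]))
  out
}

#' Project trajectory frames onto conformational modes
#'
#' Projects every frame (at full recording resolution, regardless of the
#' covariance subsampling) onto the leading eigenvectors:
#' `proj_k = v_k' (x - mean)`.
#'
#' @param ensembles list of [trajectory_ensemble()] objects.
#' @param basis a [pca_modes()] result.
#' @param n_modes number of modes to project onto (default 2).
#' @return object of class `projection_set`: a data.frame with columns
#'   `ensemble`, `origin_conformation`, `replica_id`, `frame_index`,
#'   `time_ns`, and `pc1`, `pc2`, ...; the source ensembles are attached as
#'   `attr(, "ensembles")` so extreme frames can be materialized.
#' @export
project_frames <- function(ensembles, basis, n_modes = 2L) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  stopifnot(inherits(basis, "mode_basis"), n_modes >= 1L,
            n_modes <= ncol(basis$eigenvectors))
  V <- basis$eigenvectors[, seq_len(n_modes), drop = FALSE]
  rows <- list()
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    if (dim(ens$coords)[1] < max(basis$selection))
      stop("ensemble ", e, " is not topology-compatible with the mode basis")
    M <- .flatten_frames(ens, basis$selection)
    if (basis$mass_weighted) {
      w <- sqrt(rep(atomic_number(
        ens$topology$atoms$element[basis$selection]), each = 3L))
      M <- sweep(M, 2, w, `*`)
    }
    proj <- sweep(M, 2, basis$mean_flat) %*% V
    df <- data.frame(ensemble = e,
                     origin_conformation = ens$origin_conformation,
                     replica_id = ens$replica_id,
                     frame_index = seq_len(nrow(proj)),
                     time_ns = ens$times_ns)
    for (k in seq_len(n_modes)) df[[paste0("pc", k)]] <- proj[, k]
    rows[[e]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("projection_set", class(out))
  attr(out, "ensembles") <- ensembles
  attr(out, "n_modes") <- as.integer(n_modes)
  out
}

#' Extreme conformational states along each mode
#'
#' For each projected mode, returns the frames attaining the minimal and
#' maximal projection, materialized as [structure_model()]s. Ties are broken
#' by earliest frame time.
#'
#' @param projections a [project_frames()] result.
#' @param n_modes how many modes to report (default all projected).
#' @return named list `mode1 = list(min = , max = ), mode2 = ...` of
#'   structure models; projection values in each model's label.
#' @export
extreme_states <- function(projections, n_modes = NULL) {
  stopifnot(inherits(projections, "projection_set"), nrow(projections) >= 1L)
  ensembles <- attr(projections, "ensembles")
  if (is.null(n_modes)) n_modes <- attr(projections, "n_modes")
  out <- list()
  for (k in seq_len(n_modes)) {
    v <- projections[[paste0("pc", k)]]
    pick <- function(which_fun) {
      ext <- which_fun(v)
      cand <- which(v == ext)
      cand <- cand[order(projections$time_ns[cand])][1]  # earliest time wins
      row <- projections[cand, ]
      m <- frame_model(ensembles[[row$ensemble]], row$frame_index,
                       label = sprintf("mode%d %s = %.4g", k,
                                       if (identical(which_fun, min)) "min" else "max",
                                       ext))
      m
    }
    out[[paste0("mode", k)]] <- list(min = pick(min), max = pick(max))
  }
  out
}

#' 2-D histogram of mode projections with per-ensemble outlines
#'
#' Normalized (unit total mass) 2-D histogram of the (pc1, pc2) projections
#' over all frames, plus for each origin conformation the mask of occupied
#' bins and its boundary outline (occupied bins adjacent to an unoccupied or
#' out-of-range bin in 4-neighborhood).
#'
#' @param projections a [project_frames()] result with >= 2 modes.
#' @param bins number of bins per axis (default 40), or a list
#'   `list(x = breaks, y = breaks)`.
#' @return list with `x_breaks`, `y_breaks`, `density` (matrix, sums to 1),
#'   and `outlines`: per origin conformation a list of `occupied` and
#'   `outline` logical matrices.
#' @export
projection_histogram <- function(projections, bins = 40L) {
  stopifnot(inherits(projections, "projection_set"), nrow(projections) >= 1L)
  x <- projections$pc1; y <- projections$pc2
  if (is.list(bins)) {
    bx <- bins$x; by <- bins$y
  } else {
    pad <- function(v) {
      r <- range(v)
      if (diff(r) == 0) r <- r + c(-0.5, 0.5)
      seq(r[1] - 1e-9, r[2] + 1e-9, length.out = bins + 1L)
    }
    bx <- pad(x); by <- pad(y)
  }
  ix <- findInterval(x, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE, all.inside = TRUE)
  nx <- length(bx) - 1L; ny <- length(by) - 1L
  dens <- matrix(0, nx, ny)
  for (i in seq_along(ix)) dens[ix[i], iy[i]] <- dens[ix[i], iy[i]] + 1
  dens <- dens / sum(dens)
  outline_of <- function(occ) {
    padded <- matrix(FALSE, nx + 2L, ny + 2L)
    padded[2:(nx + 1L), 2:(ny + 1L)] <- occ
    nbr_all <- padded[1:nx, 2:(ny + 1L)] & padded[3:(nx + 2L), 2:(ny + 1L)] &
      padded[2:(nx + 1L), 1:ny] & padded[2:(nx + 1L), 3:(ny + 2L)]
    occ & !nbr_all
  }
  outlines <- list()
  for (tag in unique(projections$origin_conformation)) {
    sel <- projections$origin_conformation == tag
    occ <- matrix(FALSE, nx, ny)
    occ[cbind(ix[sel], iy[sel])] <- TRUE
    outlines[[tag]] <- list(occupied = occ, outline = outline_of(occ))
  }
  list(x_breaks = bx, y_breaks = by, density = dens, outlines = outlines)
}
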