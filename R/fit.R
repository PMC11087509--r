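#' Validate a simplex weight vector
#' @param w numeric vector; must be nonnegative and sum to 1 within 1e-9.
#' @return `w`, invisibly, or an error.
#' @export
validate_weights <- function(w) {
  if (any(w < -1e-12)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  invisible(w)
}

#' Weighted voxelwise average of maps
#' @param maps list of [density_map()] objects on identical grids.
#' @param w weight vector, one per map (nonnegative, unit sum).
#' @return A [density_map()] with values `sum_i w_i * map_i`; the mask of
#'   the first masked input (if any) is carried over.
#' @export
weighted_average_map <- function(maps, w) {
  stopifnot(length(maps) >= 1L, length(maps) == length(w))
  validate_weights(w)
  g <- maps[[1]]$grid
  for (m in maps[-1])
    if (!grids_identical(g, m$grid)) stop("maps are on different grids")
  acc <- array(0, dim = g$shape)
  for (i in seq_along(maps)) acc <- acc + w[i] * maps[[i]]$values
  mask <- NULL
  for (m in maps) if (!is.null(m$mask)) { mask <- m$mask; break }
  density_map(g, acc, mask)
}

# Masked, mean-centered map values as columns of a matrix.
.masked_matrix <- function(maps, mask) {
  X <- vapply(maps, function(m) {
    v <- m$values[mask]
    v - mean(v)
  }, numeric(sum(mask)))
  as.matrix(X)
}

# rho(w) for the weighted combination, from precomputed Gram quantities:
# G = X'X, b = X't, tt = t't, all on centered masked values.
.rho_quadform <- function(w, G, b, tt) {
  denom2 <- as.numeric(t(w) %*% G %*% w) * tt
  if (denom2 <= 0) return(NA_real_)
  as.numeric(crossprod(w, b)) / sqrt(denom2)
}

# All lattice points of the unit simplex in k dims with the given step,
# as rows; ordered lexicographically.
.simplex_lattice <- function(k, step) {
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop("grid_step must divide 1 evenly")
  if (k == 1L) return(matrix(1, 1, 1))
  if (k == 2L) {
    w1 <- (0:m) / m
    return(cbind(w1, 1 - w1, deparse.level = 0))
  }
  if (k == 3L) {
    grid <- expand.grid(i = 0:m, j = 0:m)
    grid <- grid[grid$i + grid$j <= m, ]
    W <- cbind(grid$i, grid$j, m - grid$i - grid$j) / m
    return(W[order(W[, 1], W[, 2], W[, 3]), , drop = FALSE])
  }
  stop("exhaustive lattice only supported for k <= 3")
}

# Maximize rho over the simplex via the Gram form. Exhaustive lattice for
# k <= 3; multi-start bounded quasi-Newton ascent (scale-invariant in w,
# normalized afterwards) for larger k.
.optimize_weights_gram <- function(G, b, tt, grid_step = 0.01,
                                   return_surface = FALSE) {
  k <- length(b)
  if (k == 1L)
    return(list(weights = 1, rho = .rho_quadform(1, G, b, tt), surface = NULL))
  if (k <= 3L) {
    W <- .simplex_lattice(k, grid_step)
    num <- W %*% b
    den <- sqrt(pmax(rowSums((W %*% G) * W) * tt, 0))
    rho <- ifelse(den > 0, num / den, NA_real_)
    finite <- is.finite(rho)
    if (!any(finite)) stop("correlation undefined at every lattice point")
    best_rho <- max(rho[finite])
    # ties -> lexicographically smallest weight vector (rows are lex-sorted)
    cand <- which(finite & rho >= best_rho - 1e-12)
    best <- cand[1]
    surface <- NULL
    if (return_surface) {
      surface <- as.data.frame(W)
      names(surface) <- paste0("w", seq_len(k))
      surface$rho <- as.numeric(rho)
    }
    return(list(weights = as.numeric(W[best, ]), rho = as.numeric(rho[best]),
                surface = surface))
  }
  # k > 3: rho(w) is scale-invariant, so the maximum over the simplex equals
  # the maximum over the nonnegative cone. By the KKT conditions the optimal
  # support S satisfies w_S ~ G_S^{-1} b_S >= 0; enumerate supports (exact
  # for moderate k), fall back to multi-start ascent for large k.
  if (k <= 14L) {
    best_w <- NULL; best_rho <- -Inf
    for (i in seq_len(k)) {            # singletons always admissible
      r <- b[i] / sqrt(G[i, i] * tt)
      if (is.finite(r) && r > best_rho) {
        best_rho <- r
        best_w <- replace(numeric(k), i, 1)
      }
    }
    for (sz in 2:k) {
      cmb <- utils::combn(k, sz)
      for (j in seq_len(ncol(cmb))) {
        S <- cmb[, j]
        wS <- try(solve(G[S, S, drop = FALSE], b[S]), silent = TRUE)
        if (inherits(wS, "try-error")) next
        if (any(wS < 0) || sum(wS) <= 0) next
        w <- replace(numeric(k), S, wS / sum(wS))
        r <- .rho_quadform(w, G, b, tt)
        if (is.finite(r) && r > best_rho + 1e-15) {
          best_rho <- r
          best_w <- w
        }
      }
    }
    if (is.null(best_w)) stop("correlation undefined for every support")
    return(list(weights = best_w, rho = best_rho, surface = NULL))
  }
  nll <- function(w) {
    r <- .rho_quadform(w, G, b, tt)
    if (!is.finite(r)) 1e6 else -r
  }
  starts <- c(
    lapply(seq_len(k), function(i) 0.05 + 0.95 * (seq_len(k) == i)),
    list(rep(1 / k, k)),
    list({ w0 <- pmax(as.numeric(b), 0); if (sum(w0) > 0) w0 / sum(w0) else rep(1 / k, k) })
  )
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, nll, method = "L-BFGS-B",
                            lower = rep(0, k), upper = rep(1e3, k)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("weight optimization failed from every start")
  w <- pmax(best$par, 0)
  if (sum(w) == 0) w <- rep(1 / k, k)
  w <- w / sum(w)
  list(weights = w, rho = .rho_quadform(w, G, b, tt), surface = NULL)
}

#' Optimal simplex weights of ensemble maps against a target map
#'
#' Finds the nonnegative, unit-sum weights `w` maximizing the masked Pearson
#' correlation between `sum_i w_i * map_i` and the target. For up to three
#' maps the search is exhaustive over the barycentric lattice with the given
#' step (default 0.01), returning the full correlation surface (the machine
#' twin of a triangular weight-correlation plot); for more maps the lattice
#' scan is replaced by bounded ascent from multiple starts. Ties are broken
#' toward the lexicographically smallest weight vector.
#'
#' Only the direction of `w` is identifiable (Pearson correlation is
#' invariant to positive rescaling of the combined map), hence the unit-sum
#' normalization.
#'
#' @param maps list of >= 2 [density_map()] objects on the target grid.
#' @param target a masked [density_map()] (the reference region).
#' @param grid_step barycentric lattice step; must divide 1 evenly.
#' @param return_surface if `TRUE` (default for <= 3 maps) include the full
#'   scan surface as a data.frame.
#' @return list with `weights`, `rho`, `n_voxels`, and `surface` (or NULL).
#' @export
optimize_weights <- function(maps, target, grid_step = 0.01,
                             return_surface = TRUE) {
  stopifnot(length(maps) >= 2L, inherits(target, "density_map"))
  mask <- target$mask
  if (is.null(mask)) mask <- array(TRUE, dim = target$grid$shape)
  for (m in maps)
    if (!grids_identical(m$grid, target$grid))
      stop("maps are on different grids than the target")
  tv <- target$values[mask]
  tv <- tv - mean(tv)
  tt <- sum(tv^2)
  if (tt == 0) stop("target has zero variance inside the mask")
  X <- .masked_matrix(maps, mask)
  G <- crossprod(X)
  b <- as.numeric(crossprod(X, tv))
  res <- .optimize_weights_gram(G, b, tt, grid_step, return_surface)
  res$n_voxels <- sum(mask)
  res
}

#' Selection configuration for structure-set optimization
#'
#' @param n_structures number of structures in the set (>= 1).
#' @param n_replicas number of independent replica searches (default 5).
#' @param convergence_tol replicas are converged when the spread of their
#'   best correlations is at most this value (default 1e-2).
#' @param max_iterations hard cap on swap iterations per replica (default
#'   10000); reaching it sets `converged = FALSE`.
#' @param seed master RNG seed; replica r uses `seed + r`.
#' @param grid_step lattice step forwarded to the weight optimization.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(n_structures, n_replicas = 5L,
                             convergence_tol = 1e-2, max_iterations = 10000L,
                             seed = 1L, grid_step = 0.01) {
  stopifnot(n_structures >= 1L, n_replicas >= 1L, convergence_tol > 0,
            max_iterations >= 1L)
  structure(list(n_structures = as.integer(n_structures),
                 n_replicas = as.integer(n_replicas),
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), grid_step = grid_step),
            class = "selection_config")
}

# Optimize weights for a subset of pool maps given precomputed Gram data.
.subset_fit <- function(idx, G, b, tt, grid_step) {
  if (length(idx) == 1L) {
    r <- .rho_quadform(1, G[idx, idx, drop = FALSE], b[idx], tt)
    return(list(weights = 1, rho = r))
  }
  .optimize_weights_gram(G[idx, idx, drop = FALSE], b[idx], tt,
                         grid_step = grid_step, return_surface = FALSE)
}

#' Correlation-optimized structure-set selection
#'
#' Searches for the set of `n_structures` pool maps whose optimally weighted
#' average best correlates with the target. Each replica starts from a
#' uniform random subset; every iteration a random member is exchanged for a
#' random non-member, the weights of the new set are re-optimized, and the
#' move is accepted only if the correlation strictly improves. Replicas run
#' until their best correlations agree within `convergence_tol` *and* no
#' replica has accepted an improvement within the last pool-size iterations
#' (agreement is only trusted once the searches have gone quiet), or until
#' `max_iterations` is reached.
#'
#' @param pool_maps list of [density_map()] objects (the structure pool).
#' @param target a masked [density_map()].
#' @param cfg a [selection_config()].
#' @return list of class `selection_result` with `member_indices`, `weights`,
#'   `rho`, `iterations`, `replica_rhos`, `converged`, and per-replica
#'   accepted-correlation traces in `traces`.
#' @export
optimize_structure_set <- function(pool_maps, target, cfg) {
  stopifnot(inherits(cfg, "selection_config"))
  P <- length(pool_maps)
  N <- cfg$n_structures
  if (N > P) stop("n_structures exceeds pool size")
  mask <- target$mask
  if (is.null(mask)) mask <- array(TRUE, dim = target$grid$shape)
  tv <- target$values[mask]; tv <- tv - mean(tv); tt <- sum(tv^2)
  if (tt == 0) stop("target has zero variance inside the mask")
  X <- .masked_matrix(pool_maps, mask)
  G <- crossprod(X)
  b <- as.numeric(crossprod(X, tv))

  # per-replica RNG streams: replica r seeded with seed + r
  rng_states <- vector("list", cfg$n_replicas)
  replicas <- vector("list", cfg$n_replicas)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  for (r in seq_len(cfg$n_replicas)) {
    set.seed(cfg$seed + r)
    members <- sample.int(P, N)
    fit <- .subset_fit(members, G, b, tt, cfg$grid_step)
    if (!is.finite(fit$rho)) stop("non-finite correlation at initialization")
    replicas[[r]] <- list(members = members, weights = fit$weights,
                          rho = fit$rho, trace = fit$rho)
    rng_states[[r]] <- get(".Random.seed", .GlobalEnv)
  }

  burn_in <- P
  iterations <- 0L
  converged <- FALSE
  last_accept <- 0L
  while (iterations < cfg$max_iterations) {
    iterations <- iterations + 1L
    for (r in seq_len(cfg$n_replicas)) {
      assign(".Random.seed", rng_states[[r]], .GlobalEnv)
      st <- replicas[[r]]
      out_pos <- if (N == 1L) 1L else sample.int(N, 1L)
      non_members <- setdiff(seq_len(P), st$members)
      if (!length(non_members)) { rng_states[[r]] <- get(".Random.seed", .GlobalEnv); next }
      incoming <- non_members[sample.int(length(non_members), 1L)]
      proposal <- st$members
      proposal[out_pos] <- incoming
      fit <- .subset_fit(proposal, G, b, tt, cfg$grid_step)
      if (is.finite(fit$rho) && fit$rho > st$rho) {   # strict improvement
        st$members <- proposal
        st$weights <- fit$weights
        st$rho <- fit$rho
        last_accept <- iterations
      }
      st$trace <- c(st$trace, st$rho)
      replicas[[r]] <- st
      rng_states[[r]] <- get(".Random.seed", .GlobalEnv)
    }
    if (iterations >= burn_in && iterations - last_accept >= P) {
      rhos <- vapply(replicas, `[[`, numeric(1), "rho")
      if (max(rhos) - min(rhos) <= cfg$convergence_tol) {
        converged <- TRUE
        break
      }
    }
  }

  rhos <- vapply(replicas, `[[`, numeric(1), "rho")
  best_r <- which.max(rhos)
  st <- replicas[[best_r]]
  ord <- order(st$members)
  structure(list(member_indices = st$members[ord],
                 weights = st$weights[ord],
                 rho = st$rho,
                 iterations = iterations,
                 replica_rhos = rhos,
                 converged = converged,
                 traces = lapply(replicas, `[[`, "trace")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: N = %d, rho = %.5f (%s after %d iterations)\n",
              length(x$member_indices), x$rho,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  members:", paste(x$member_indices, collapse = ", "), "\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  cat("  replica rhos:", paste(sprintf("%.5f", x$replica_rhos), collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive-enumeration oracle for structure-set selection
#'
#' Enumerates every size-`n` subset of the pool, optimizes weights for each,
#' and returns the exact maximizer. Intended as a test oracle for
#' [optimize_structure_set()] on small pools.
#'
#' @param pool_maps list of [density_map()] objects.
#' @param target a masked [density_map()].
#' @param n subset size.
#' @param grid_step lattice step for the per-subset weight optimization.
#' @param max_subsets refuse to enumerate more than this many subsets
#'   (default 20000).
#' @return list of class `selection_result` (iterations = number of subsets
#'   enumerated; converged = TRUE).
#' @export
brute_force_select <- function(pool_maps, target, n, grid_step = 0.01,
                               max_subsets = 20000) {
  P <- length(pool_maps)
  stopifnot(n >= 1L, n <= P)
  if (choose(P, n) > max_subsets)
    stop("enumeration cap exceeded: choose(", P, ", ", n, ") subsets")
  mask <- target$mask
  if (is.null(mask)) mask <- array(TRUE, dim = target$grid$shape)
  tv <- target$values[mask]; tv <- tv - mean(tv); tt <- sum(tv^2)
  if (tt == 0) stop("target has zero variance inside the mask")
  X <- .masked_matrix(pool_maps, mask)
  G <- crossprod(X)
  b <- as.numeric(crossprod(X, tv))
  subsets <- utils::combn(P, n)
  best <- NULL
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    fit <- .subset_fit(idx, G, b, tt, grid_step)
    if (is.finite(fit$rho) && (is.null(best) || fit$rho > best$rho))
      best <- list(idx = idx, rho = fit$rho, weights = fit$weights)
  }
  if (is.null(best)) stop("correlation undefined for every subset")
  structure(list(member_indices = best$idx, weights = best$weights,
                 rho = best$rho, iterations = ncol(subsets),
                 replica_rhos = best$rho, converged = TRUE,
                 traces = list()),
            class = "selection_result")
}

#' Maximum correlation as a function of set size
#'
#' Runs [optimize_structure_set()] for each requested set size and tabulates
#' the best correlation, together with two reference values: the optimally
#' weighted initial structures (when given) and the full equally weighted
#' pool ensemble.
#'
#' @param pool_maps list of [density_map()] objects.
#' @param target a masked [density_map()].
#' @param n_values integer vector of set sizes.
#' @param cfg a [selection_config()] (its `n_structures` is overridden).
#' @param initial_maps optional list of maps of the initial structures; when
#'   given, their optimally weighted correlation is reported.
#' @return data.frame `(n, rho, converged)` with attributes
#'   `rho_full_ensemble` and (optionally) `rho_initial`, plus the
#'   per-n selection results in `attr(, "results")`.
#' @export
best_n_curve <- function(pool_maps, target, n_values, cfg,
                         initial_maps = NULL) {
  stopifnot(all(n_values >= 1L), all(n_values <= length(pool_maps)))
  results <- list()
  rows <- lapply(n_values, function(n) {
    cfg_n <- cfg; cfg_n$n_structures <- as.integer(n)
    res <- optimize_structure_set(pool_maps, target, cfg_n)
    results[[as.character(n)]] <<- res
    data.frame(n = n, rho = res$rho, converged = res$converged)
  })
  out <- do.call(rbind, rows)
  full <- weighted_average_map(pool_maps,
                               rep(1 / length(pool_maps), length(pool_maps)))
  attr(out, "rho_full_ensemble") <-
    map_correlation(full, target, mask = target$mask)$rho
  if (!is.null(initial_maps) && length(initial_maps) >= 2L)
    attr(out, "rho_initial") <-
      optimize_weights(initial_maps, target, cfg$grid_step,
                       return_surface = FALSE)$rho
  else if (!is.null(initial_maps))
    attr(out, "rho_initial") <-
      map_correlation(initial_maps[[1]], target, mask = target$mask)$rho
  attr(out, "results") <- results
  out
}
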