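#' Trajectory ensemble container
#'
#' Holds time-stamped coordinate frames sharing one topology, tagged by the
#' conformation the simulation was started from and a replica id. Frame
#' coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom;
#' frame times are in nanoseconds, strictly increasing.
#'
#' @param topology a [structure_model()] defining atom identity and order.
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single frame may
#'   be given as an `n_atoms x 3` matrix).
#' @param times_ns numeric vector of frame times in ns, strictly increasing,
#'   nonnegative.
#' @param origin_conformation label of the starting conformation.
#' @param replica_id integer replica index.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(topology, coords, times_ns,
                                origin_conformation = "", replica_id = 1L) {
  stopifnot(inherits(topology, "structure_model"))
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("coordinate count per frame (", dim(coords)[1],
         ") does not match topology atom count (", nrow(topology$atoms), ")")
  times_ns <- as.numeric(times_ns)
  if (length(times_ns) != dim(coords)[3])
    stop("length(times_ns) must equal the number of frames")
  if (any(times_ns < 0)) stop("frame times must be nonnegative")
  if (length(times_ns) > 1L && any(diff(times_ns) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times_ns = times_ns,
                 origin_conformation = as.character(origin_conformation),
                 replica_id = as.integer(replica_id)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "trajectory_ensemble: %d frames x %d atoms, t = %.4g..%.4g ns (conf '%s', replica %d)\n",
    n_frames(x), dim(x$coords)[1], min(x$times_ns), max(x$times_ns),
    x$origin_conformation, x$replica_id))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [trajectory_ensemble()].
#' @return integer.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame as a coordinate matrix
#' @param ensemble a [trajectory_ensemble()].
#' @param i frame index.
#' @return numeric matrix n_atoms x 3.
#' @export
frame_coords <- function(ensemble, i) {
  stopifnot(i >= 1L, i <= n_frames(ensemble))
  ensemble$coords[, , i, drop = TRUE]
}

#' Extract one frame as a structure model
#' @param ensemble a [trajectory_ensemble()].
#' @param i frame index.
#' @param label optional label for the returned model.
#' @return a [structure_model()].
#' @export
frame_model <- function(ensemble, i, label = NULL) {
  if (is.null(label))
    label <- sprintf("%s/r%d@%.4gns", ensemble$origin_conformation,
                     ensemble$replica_id, ensemble$times_ns[i])
  set_coords(structure_model(ensemble$topology$atoms, label = label),
             frame_coords(ensemble, i))
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    elem <- vapply(toks, `[`, character(1), 1L)
    t_ns <- NA_real_
    m <- regmatches(comment, regexec("time[ =]+([0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 2L) t_ns <- as.numeric(m[2])
    frames[[length(frames) + 1L]] <- list(elem = elem, xyz = xyz, time = t_ns)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in XYZ file ", path)
  frames
}

#' Read trajectory frames into an ensemble
#'
#' Supports multi-model PDB and multi-frame whitespace XYZ files. Frame times
#' are taken from metadata when present (XYZ comment lines of the form
#' `time = <ns>`), otherwise assigned as `frame_index * timestep_ns` starting
#' at zero.
#'
#' @param paths one or more trajectory file paths, concatenated in order.
#' @param topology a [structure_model()] the frames must be compatible with.
#' @param timestep_ns recording interval used when files carry no time
#'   metadata (default 0.005 ns = 5 ps).
#' @param origin_conformation,replica_id tags stored on the ensemble.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory <- function(paths, topology, timestep_ns = 0.005,
                            origin_conformation = "", replica_id = 1L) {
  stopifnot(inherits(topology, "structure_model"))
  n_atoms <- nrow(topology$atoms)
  coord_list <- list(); times <- numeric(0)
  for (p in paths) {
    is_xyz <- grepl("\\.xyz$", p, ignore.case = TRUE)
    if (is_xyz) {
      frames <- .read_xyz_frames(p)
      for (fr in frames) {
        if (nrow(fr$xyz) != n_atoms)
          stop("frame atom count ", nrow(fr$xyz), " does not match topology (",
               n_atoms, ") in ", p)
        coord_list[[length(coord_list) + 1L]] <- fr$xyz
        times <- c(times, fr$time)
      }
    } else {
      models <- read_pdb(p, multi = TRUE)
      for (m in models) {
        if (nrow(m$atoms) != n_atoms)
          stop("frame atom count ", nrow(m$atoms), " does not match topology (",
               n_atoms, ") in ", p)
        coord_list[[length(coord_list) + 1L]] <- coords(m)
        times <- c(times, NA_real_)
      }
    }
  }
  if (any(is.na(times)))
    times[is.na(times)] <- (which(is.na(times)) - 1L) * timestep_ns
  arr <- array(unlist(coord_list), dim = c(n_atoms, 3L, length(coord_list)))
  trajectory_ensemble(topology, arr, times,
                      origin_conformation = origin_conformation,
                      replica_id = replica_id)
}

#' Write an ensemble as a multi-frame XYZ file
#' @param ensemble a [trajectory_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  elem <- ensemble$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, i)
    writeLines(c(as.character(length(elem)),
                 sprintf("time = %.6f", ensemble$times_ns[i]),
                 sprintf("%-2s %12.6f %12.6f %12.6f",
                         elem, xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}
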