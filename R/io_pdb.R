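#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Coordinates are in Angstrom.
#' The element is taken from the element column (77-78) when present, else
#' inferred from the atom name via [infer_element()]. Files with MODEL
#' blocks yield one model per block.
#'
#' @param path path to a PDB file.
#' @param multi if `TRUE` always return a list of models; if `FALSE`
#'   (default) a single-model file returns the bare [structure_model()].
#' @return A [structure_model()] or a list of them (one per MODEL block).
#' @export
read_pdb <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    substr(lines, 1, 4) == "ATOM" & nchar(trimws(rec)) == 4
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # split into MODEL blocks; atoms before any MODEL belong to block 0
  model_id <- cumsum(substr(lines, 1, 5) == "MODEL")
  blocks <- split(lines[is_atom], model_id[is_atom])

  parse_block <- function(bl) {
    atom_name <- trimws(substr(bl, 13, 16))
    element <- trimws(substr(bl, 77, 78))
    no_el <- element == "" | is.na(element)
    if (any(no_el)) element[no_el] <- infer_element(atom_name[no_el])
    x <- as.numeric(substr(bl, 31, 38))
    y <- as.numeric(substr(bl, 39, 46))
    z <- as.numeric(substr(bl, 47, 54))
    if (any(!is.finite(c(x, y, z))))
      stop("non-numeric coordinates in ", path)
    structure_model(data.frame(
      atom_name = atom_name,
      element = element,
      residue_name = trimws(substr(bl, 18, 20)),
      residue_index = as.integer(trimws(substr(bl, 23, 26))),
      chain_id = substr(bl, 22, 22),
      x = x, y = y, z = z,
      stringsAsFactors = FALSE))
  }

  models <- lapply(blocks, parse_block)
  names(models) <- NULL
  if (length(models) == 1L && !multi) models[[1]] else models
}

.format_pdb_coord <- function(v) {
  out <- sprintf("%8.3f", v)
  if (any(nchar(out) > 8L))
    stop("coordinate out of PDB fixed-column range (-999.999..9999.999): ",
         v[which(nchar(out) > 8L)[1]])
  out
}

.pdb_atom_lines <- function(model) {
  a <- model$atoms
  nm <- a$atom_name
  # PDB convention: 1-3 character names start in column 14
  nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %s%s%s  1.00  0.00          %2s",
          seq_len(nrow(a)) %% 100000L, nm4, substr(a$residue_name, 1, 3),
          substr(paste0(a$chain_id, " "), 1, 1), a$residue_index %% 10000L,
          .format_pdb_coord(a$x), .format_pdb_coord(a$y),
          .format_pdb_coord(a$z), toupper(a$element))
}

#' Write one or more models to a PDB file
#'
#' Writes standard fixed-column ATOM records; a list of models is written as
#' MODEL/ENDMDL blocks. Coordinates outside the fixed-column range raise an
#' error rather than being silently truncated.
#'
#' @param model a [structure_model()] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  if (inherits(model, "structure_model")) model <- list(model)
  if (!length(model)) stop("no models to write")
  lines <- character(0)
  multi <- length(model) > 1L
  for (m in seq_along(model)) {
    stopifnot(inherits(model[[m]], "structure_model"))
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, .pdb_atom_lines(model[[m]]))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
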