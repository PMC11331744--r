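#' Read an XYZ file
#'
#' Plain XYZ: first line atom count, second line a free-text comment, then one
#' `element x y z` row per atom (coordinates in Angstrom).
#'
#' @param path Path to an `.xyz` file.
#' @return An atoms tibble with columns `element`, `x`, `y`, `z`,
#'   `formal_charge` (0; XYZ carries no charge metadata).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 1) stop("malformed XYZ header in ", path, call. = FALSE)
  rows <- strsplit(trimws(lines[seq(3, 2 + n)]), "\\s+")
  tibble::tibble(
    element = vapply(rows, `[[`, "", 1L),
    x = vapply(rows, function(r) as.numeric(r[2]), 0),
    y = vapply(rows, function(r) as.numeric(r[3]), 0),
    z = vapply(rows, function(r) as.numeric(r[4]), 0),
    formal_charge = 0L
  )
}

#' Write an XYZ file
#'
#' @param atoms Atoms tibble (`element`, `x`, `y`, `z`).
#' @param path Output path.
#' @param comment Comment line (line 2 of the file).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(atoms, path, comment = "") {
  body <- sprintf("%-3s %14.8f %14.8f %14.8f",
                  atoms$element, atoms$x, atoms$y, atoms$z)
  writeLines(c(as.character(nrow(atoms)), comment, body), path)
  invisible(path)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records through \pkg{bio3d} when available, falling back
#' to fixed-column parsing otherwise. The element column (77-78) is
#' authoritative for the element symbol; coordinates are Angstrom.
#'
#' @param path Path to a `.pdb` file.
#' @return An atoms tibble (`element`, `x`, `y`, `z`, `formal_charge`).
#' @export
read_pdb <- function(path) {
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    elem <- trimws(a$elesy)
    elem[elem == ""] <- substr(trimws(a$elety[elem == ""]), 1, 1)
    return(tibble::tibble(
      element = .normalise_element(elem),
      x = a$x, y = a$y, z = a$z,
      formal_charge = .parse_pdb_charge(a$charge)
    ))
  }
  lines <- grep("^(ATOM|HETATM)", readLines(path), value = TRUE)
  if (!length(lines)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  tibble::tibble(
    element = .normalise_element(trimws(substr(lines, 77, 78))),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    formal_charge = .parse_pdb_charge(trimws(substr(lines, 79, 80)))
  )
}

.normalise_element <- function(e) {
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

# PDB charge column is e.g. "1+", "2-", or blank.
.parse_pdb_charge <- function(ch) {
  ch <- as.character(ch)
  out <- integer(length(ch))
  has <- !is.na(ch) & grepl("^[0-9][+-]$", ch)
  sgn <- ifelse(substr(ch[has], 2, 2) == "-", -1L, 1L)
  out[has] <- sgn * as.integer(substr(ch[has], 1, 1))
  out
}

#' Read a molecular structure (format by extension)
#'
#' @param path Path ending in `.xyz` or `.pdb`.
#' @return An atoms tibble.
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    xyz = read_xyz(path),
    pdb = read_pdb(path),
    stop("unsupported structure format: .", ext, call. = FALSE)
  )
}

#' Write capped fragments and a JSON manifest
#'
#' One XYZ file per capped fragment (`fragment_001.xyz`, ...) plus
#' `manifest.json` recording the cut bonds (atom-index pairs), per-fragment
#' sizes with and without caps, and volumes.
#'
#' @param fragments A fragment set as returned by [extract_fragments()] or
#'   [fragment_system()].
#' @param dir Output directory (created if absent).
#' @param cuts Optional tibble of cut bonds (`from`, `to`).
#' @return The manifest path, invisibly.
#' @export
write_fragments <- function(fragments, dir, cuts = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frs <- if (inherits(fragments, "molfrag_result")) fragments$fragments else fragments
  for (k in seq_along(frs$geometry)) {
    write_xyz(frs$geometry[[k]],
              file.path(dir, sprintf("fragment_%03d.xyz", k)),
              comment = sprintf("fragment %d: %d atoms (+%d caps)", k,
                                frs$n_atoms[k], frs$n_caps[k]))
  }
  manifest <- list(
    n_fragments = length(frs$geometry),
    sizes_bare = frs$n_atoms,
    sizes_with_caps = frs$n_atoms + frs$n_caps,
    volumes = frs$volume,
    cut_bonds = if (is.null(cuts)) list() else
      purrr::map2(cuts$from, cuts$to, c)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
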