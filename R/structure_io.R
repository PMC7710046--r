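# PDB input/output and van der Waals radius assignment.
#
# All coordinates are stored in nanometres internally; PDB files are in
# Angstrom, so parsing divides by 10 and writing multiplies by 10.

#' Van der Waals radius table
#'
#' Returns the element radius table used to build the hard-sphere
#' representation of a structure, in nanometres. The core values are the
#' Bondi (1964) set; a few metal ions common in protein structures are
#' included with their widely used literature values. The table can be
#' extended or overridden via the `override` argument, e.g. to encode
#' oversized pseudo-domain spheres in coarse-grained mock structures.
#'
#' @param override optional named numeric vector of radii (nm) that is
#'   merged over the built-in table; names are element symbols.
#' @return named numeric vector of radii in nm.
#' @examples
#' vdw_radii()[["C"]]            # 0.170
#' vdw_radii(c(Q = 1.5))[["Q"]]  # custom pseudo-atom
#' @export
vdw_radii <- function(override = NULL) {
  tab <- c(
    H = 0.120, He = 0.140,
    C = 0.170, N = 0.155, O = 0.152, F = 0.147, Ne = 0.154,
    Si = 0.210, P = 0.180, S = 0.180, Cl = 0.175, Ar = 0.188,
    As = 0.185, Se = 0.190, Br = 0.185, Kr = 0.202,
    Te = 0.206, I = 0.198, Xe = 0.216,
    # common ions / metals in biomolecular structures
    Li = 0.182, Na = 0.227, K = 0.275, Mg = 0.173, Ca = 0.231,
    Zn = 0.139, Cu = 0.140, Ni = 0.163, Fe = 0.194, Mn = 0.205
  )
  if (!is.null(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      stop("radius override must be a named numeric vector")
    tab[names(override)] <- override
  }
  tab
}

#' Look up the van der Waals radius of an element
#'
#' Lookup is case-insensitive ("FE" and "Fe" both resolve to iron). An
#' unrecognized element is an error unless `default` supplies a fallback
#' radius.
#'
#' @param element element symbol (scalar or vector).
#' @param table radius table as returned by [vdw_radii()].
#' @param default optional fallback radius (nm) for elements absent from the
#'   table; `NULL` (the default) makes unknown elements an error.
#' @return numeric vector of radii in nm.
#' @examples
#' element_radius("C")  # 0.170
#' element_radius(c("H", "O"))
#' @export
element_radius <- function(element, table = vdw_radii(), default = NULL) {
  idx <- match(toupper(element), toupper(names(table)))
  r <- unname(table[idx])
  if (anyNA(idx)) {
    if (is.null(default)) {
      bad <- unique(element[is.na(idx)])
      stop("no van der Waals radius for element(s): ",
           paste(bad, collapse = ", "),
           " (supply `default` or extend the table)")
    }
    stopifnot(is.numeric(default), default > 0)
    r[is.na(idx)] <- default
  }
  r
}

#' Construct a structure object
#'
#' A structure is an ordered collection of hard-sphere atoms: element symbol,
#' centre position in nm, and van der Waals radius in nm. This is the
#' in-memory representation every scanning function operates on.
#'
#' @param element character vector of element symbols.
#' @param x,y,z atom centre coordinates, nm.
#' @param radius sphere radii, nm; defaults to [element_radius()] lookups.
#' @param serial integer record indices; defaults to `1:n`.
#' @param label free-text provenance label.
#' @return an object of class `afm_structure`: a list with an `atoms`
#'   data frame (`serial`, `element`, `x`, `y`, `z`, `radius`) and a `label`.
#' @export
afm_structure <- function(element, x, y, z, radius = element_radius(element),
                          serial = seq_along(element), label = "") {
  n <- length(element)
  if (n < 1L) stop("a structure needs at least one atom")
  stopifnot(length(x) == n, length(y) == n, length(z) == n,
            length(radius) == n)
  if (any(!is.finite(c(x, y, z)))) stop("atom coordinates must be finite")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("all van der Waals radii must be positive and finite")
  structure(
    list(atoms = data.frame(serial = as.integer(serial),
                            element = as.character(element),
                            x = as.numeric(x), y = as.numeric(y),
                            z = as.numeric(z),
                            radius = as.numeric(radius),
                            stringsAsFactors = FALSE),
         label = label),
    class = "afm_structure")
}

#' @export
print.afm_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<afm_structure> %d atoms%s\n", nrow(a),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  elements: %s\n",
              paste(names(sort(table(a$element), decreasing = TRUE)),
                    collapse = " ")))
  cat(sprintf("  extent (nm): x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
              min(a$x), max(a$x), min(a$y), max(a$y), min(a$z), max(a$z)))
  invisible(x)
}

#' Construct a trajectory object
#'
#' An ordered list of structures (frames) with identical atom counts and
#' element sequences, as produced by multi-MODEL PDB files.
#'
#' @param frames list of `afm_structure` objects.
#' @return an object of class `afm_trajectory`.
#' @export
afm_trajectory <- function(frames) {
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "afm_structure")))
    stop("all frames must be afm_structure objects")
  el0 <- frames[[1L]]$atoms$element
  for (k in seq_along(frames)) {
    elk <- frames[[k]]$atoms$element
    if (length(elk) != length(el0) || !identical(elk, el0))
      stop("trajectory frames are inconsistent: frame ", k,
           " differs from frame 1 in atom count or element sequence")
  }
  structure(list(frames = frames), class = "afm_trajectory")
}

#' @export
print.afm_trajectory <- function(x, ...) {
  cat(sprintf("<afm_trajectory> %d frame(s), %d atoms/frame\n",
              length(x$frames), nrow(x$frames[[1L]]$atoms)))
  invisible(x)
}

#' @export
length.afm_trajectory <- function(x) length(x$frames)

# Infer an element symbol from the PDB atom-name field (columns 13-16).
# Digits are stripped; a two-letter match against the radius table wins
# (metals like FE, ZN occupy columns 13-14), otherwise the first letter is
# taken (handles names like "1HB1", " CA ").
infer_element <- function(name, table) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(s)) return("")
    two <- substr(s, 1L, 2L)
    if (nchar(s) >= 2L && toupper(two) %in% toupper(names(table))) {
      # only accept the two-letter reading when the raw name starts in
      # column 13 (left-justified), the PDB convention for two-letter symbols
      if (substr(nm, 1L, 1L) != " ") return(two)
    }
    substr(s, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

normalize_element <- function(el, table) {
  idx <- match(toupper(el), toupper(names(table)))
  out <- el
  out[!is.na(idx)] <- names(table)[idx[!is.na(idx)]]
  out
}

#' Parse a PDB file or text into a trajectory
#'
#' Reads fixed-column PDB text. Each `MODEL`...`ENDMDL` block becomes one
#' frame; a file without `MODEL` records yields exactly one frame. `ATOM` and
#' `HETATM` records are both scanned; all other record types are ignored.
#' Coordinates are converted from Angstrom to nanometres. The element is
#' taken from columns 77-78 when present, otherwise inferred from the
#' atom-name field. Only the first alternate location of each atom is kept;
#' occupancy is ignored.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param exclude_water drop residues named HOH/WAT/DOD.
#' @param hetatm include HETATM records (default TRUE; ligands and
#'   nucleotides are part of the scanned complex).
#' @param radii radius table, see [vdw_radii()].
#' @param default_radius fallback radius (nm) for elements not in the table;
#'   `NULL` makes them an error.
#' @return an `afm_trajectory` (use `$frames[[1]]` for a single structure).
#' @export
parse_pdb <- function(source, exclude_water = FALSE, hetatm = TRUE,
                      radii = vdw_radii(), default_radius = NULL) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(source)
  }
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | (hetatm & rec == "HETATM")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records found in PDB input")

  # frame id: number of ENDMDL records seen strictly before each line
  frame_id <- cumsum(is_endmdl) - is_endmdl * 1L
  frame_of_atom <- frame_id[is_atom] + 1L
  al <- lines[is_atom]
  pad <- function(s, n) formatC(s, width = -n)  # right-pad for safe substr
  al <- vapply(al, pad, character(1), n = 80L, USE.NAMES = FALSE)

  name    <- substr(al, 13L, 16L)
  altloc  <- substr(al, 17L, 17L)
  resname <- trimws(substr(al, 18L, 20L))
  xyz_x   <- as.numeric(substr(al, 31L, 38L))
  xyz_y   <- as.numeric(substr(al, 39L, 46L))
  xyz_z   <- as.numeric(substr(al, 47L, 54L))
  elem    <- trimws(substr(al, 77L, 78L))
  if (any(!is.finite(c(xyz_x, xyz_y, xyz_z))))
    stop("malformed coordinate field in ATOM/HETATM record")

  miss <- !nzchar(elem)
  if (any(miss)) elem[miss] <- infer_element(name[miss], radii)
  elem <- normalize_element(elem, radii)

  keep <- rep(TRUE, length(al))
  if (exclude_water) keep <- keep & !(resname %in% c("HOH", "WAT", "DOD"))
  # first alternate location per atom site (chain+resSeq+resName+name key)
  key <- paste(substr(al, 22L, 22L), substr(al, 23L, 26L), resname, name,
               frame_of_atom)
  has_alt <- altloc != " " & nzchar(altloc)
  if (any(has_alt)) {
    first_alt <- tapply(altloc[has_alt], key[has_alt], function(a) a[[1L]])
    keep[has_alt] <- keep[has_alt] &
      altloc[has_alt] == unname(first_alt[key[has_alt]])
  }
  if (!any(keep)) stop("no atoms left after filtering")

  radius <- element_radius(elem[keep], table = radii,
                           default = default_radius)
  fid <- frame_of_atom[keep]
  lab <- if (length(source) == 1L && !grepl("\n", source) &&
             file.exists(source)) basename(source) else "pdb-text"
  frames <- lapply(sort(unique(fid)), function(k) {
    sel <- fid == k
    afm_structure(element = elem[keep][sel],
                  x = xyz_x[keep][sel] / 10,
                  y = xyz_y[keep][sel] / 10,
                  z = xyz_z[keep][sel] / 10,
                  radius = radius[sel],
                  label = sprintf("%s#%d", lab, k))
  })
  afm_trajectory(frames)
}

format_atom_line <- function(i, el, x, y, z) {
  # coordinates arrive in nm; PDB columns hold Angstrom with %8.3f
  ax <- x * 10; ay <- y * 10; az <- z * 10
  if (any(c(ax, ay, az) > 9999.999) || any(c(ax, ay, az) < -999.999))
    stop("coordinate overflows the PDB 8.3 column format")
  name <- if (nchar(el) >= 2L) sprintf("%-4s", substr(el, 1L, 4L))
          else sprintf(" %-3s", el)
  sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L, name, "UNK", "A", i %% 10000L, ax, ay, az, 1, 0,
          toupper(el))
}

#' Write a structure or trajectory to PDB text
#'
#' Emits standards-conformant fixed-column `ATOM` records (wrapped in
#' `MODEL`/`ENDMDL` blocks for trajectories) that [parse_pdb()] reads back
#' losslessly to the 0.001-Angstrom column precision. Intended for test
#' fixtures and for exporting generated synthetic structures.
#'
#' @param x an `afm_structure` or `afm_trajectory`.
#' @param file optional path; when `NULL` the text is only returned.
#' @return character vector of PDB lines, invisibly when `file` is given.
#' @export
write_fixture_pdb <- function(x, file = NULL) {
  if (inherits(x, "afm_structure")) x <- afm_trajectory(list(x))
  if (!inherits(x, "afm_trajectory"))
    stop("x must be an afm_structure or afm_trajectory")
  multi <- length(x$frames) > 1L
  out <- "REMARK   generated by afmscan::write_fixture_pdb"
  lab <- x$frames[[1L]]$label
  if (nzchar(lab)) out <- c(out, paste0("REMARK   ", lab))
  for (k in seq_along(x$frames)) {
    a <- x$frames[[k]]$atoms
    body <- vapply(seq_len(nrow(a)), function(i)
      format_atom_line(i, a$element[i], a$x[i], a$y[i], a$z[i]), character(1))
    if (multi) out <- c(out, sprintf("MODEL     %4d", k), body, "ENDMDL")
    else out <- c(out, body)
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
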