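# Multi-model PDB ensemble input/output.
#
# An Ensemble holds an atom table shared by all frames plus a
# n_atoms x 3 x n_frames coordinate array (Angstrom).  Atom order is
# identical across frames; this is validated on read and construction.

#' Construct a conformational ensemble
#'
#' Builds the in-memory container used by all trajectory analyses: a fixed
#' atom table plus one coordinate set per frame.  Every frame must have the
#' same atoms in the same order.
#'
#' @param atoms data.frame with columns `chain`, `resnum`, `resname`,
#'   `atom_name`, `element` (one row per atom).
#' @param coords numeric array of dimension `c(nrow(atoms), 3, n_frames)`,
#'   coordinates in Angstrom.
#' @param source_path origin of the data; `"synthetic"` for generated
#'   ensembles.
#' @return An object of class `"Ensemble"` with fields `atoms`, `coords`,
#'   `frame_count` and `source_path`.
#' @seealso [read_ensemble()], [write_ensemble()],
#'   [simulate_breathing_ensemble()]
#' @export
ensemble <- function(atoms, coords, source_path = "synthetic") {
  req <- c("chain", "resnum", "resname", "atom_name", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(atoms)) {
    stop("coords has ", dim(coords)[1], " atoms but atom table has ",
         nrow(atoms))
  }
  if (dim(coords)[3] < 1L) stop("an ensemble needs at least one frame")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  atoms$resnum <- as.integer(atoms$resnum)
  if (any(atoms$resnum < 1L)) {
    stop("residue numbers must be >= 1 (found ", min(atoms$resnum), ")")
  }
  # residue numbers unique within a chain: the same (chain, resnum) may span
  # several atom rows, but must carry one residue name only
  key <- paste(atoms$chain, atoms$resnum)
  if (any(tapply(atoms$resname, key, function(x) length(unique(x))) > 1L)) {
    stop("residue number reused with a different residue name within a chain")
  }
  structure(
    list(atoms = atoms, coords = coords,
         frame_count = dim(coords)[3], source_path = source_path),
    class = "Ensemble"
  )
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", x$frame_count, "frame(s),", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' @export
dim.Ensemble <- function(x) dim(x$coords)

# ---- PDB fixed-width records -------------------------------------------

.parse_atom_line <- function(line) {
  list(
    atom_name = trimws(substr(line, 13, 16)),
    altloc    = substr(line, 17, 17),
    resname   = trimws(substr(line, 18, 20)),
    chain     = substr(line, 22, 22),
    resnum    = suppressWarnings(as.integer(substr(line, 23, 26))),
    icode     = substr(line, 27, 27),
    x = as.numeric(substr(line, 31, 38)),
    y = as.numeric(substr(line, 39, 46)),
    z = as.numeric(substr(line, 47, 54)),
    element = trimws(substr(line, 77, 78))
  )
}

# element inferred from the atom name when columns 77-78 are blank:
# strip digits, take the first character ("CA" -> C, "1HB" -> H)
.infer_element <- function(atom_name) {
  stripped <- gsub("[0-9']", "", atom_name)
  toupper(substr(stripped, 1, 1))
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single frame.  All models must contain the same
#' atoms in the same order.  Alternate locations other than blank or `"A"`
#' are discarded; files using insertion codes are rejected.  Hydrogens are
#' kept in the atom table (distance calculations ignore them).
#'
#' @param path path to a PDB file.
#' @param chain_filter optional character vector of chain identifiers to
#'   keep; an empty selection is an error.
#' @return An [ensemble()] object.
#' @export
read_ensemble <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))

  if (length(model_starts) == 0L) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    blocks <- mapply(function(s, e) {
      idx <- seq(s, e)
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  if (length(blocks[[1]]) == 0L) stop("no ATOM records found in ", path)

  parse_block <- function(idx) {
    recs <- lapply(lines[idx], .parse_atom_line)
    df <- data.frame(
      atom_name = vapply(recs, `[[`, "", "atom_name"),
      altloc    = vapply(recs, `[[`, "", "altloc"),
      resname   = vapply(recs, `[[`, "", "resname"),
      chain     = vapply(recs, `[[`, "", "chain"),
      resnum    = vapply(recs, function(r) r$resnum, 1L),
      icode     = vapply(recs, `[[`, "", "icode"),
      x = vapply(recs, `[[`, 0, "x"),
      y = vapply(recs, `[[`, 0, "y"),
      z = vapply(recs, `[[`, 0, "z"),
      element = vapply(recs, `[[`, "", "element"),
      stringsAsFactors = FALSE
    )
    if (any(df$icode != " ")) {
      stop("insertion codes are not supported (found in ", path, ")")
    }
    df <- df[df$altloc %in% c(" ", "A"), , drop = FALSE]
    df
  }

  frames <- lapply(blocks, parse_block)
  ref <- frames[[1]]
  sig <- function(df) paste(df$chain, df$resnum, df$atom_name, sep = "|")
  ref_sig <- sig(ref)
  for (m in seq_along(frames)) {
    if (nrow(frames[[m]]) != nrow(ref)) {
      stop("structural inconsistency: model ", m, " has ",
           nrow(frames[[m]]), " atoms, expected ", nrow(ref))
    }
    if (!identical(sig(frames[[m]]), ref_sig)) {
      stop("structural inconsistency: model ", m,
           " atom identities differ from model 1")
    }
  }

  keep <- rep(TRUE, nrow(ref))
  if (!is.null(chain_filter)) {
    keep <- ref$chain %in% chain_filter
    if (!any(keep)) {
      stop("chain filter {", paste(chain_filter, collapse = ","),
           "} selects no atoms")
    }
  }

  n_atoms <- sum(keep)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, length(frames)))
  for (m in seq_along(frames)) {
    fr <- frames[[m]][keep, , drop = FALSE]
    coords[, , m] <- cbind(fr$x, fr$y, fr$z)
  }
  atoms <- ref[keep, c("chain", "resnum", "resname", "atom_name", "element"),
               drop = FALSE]
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- .infer_element(atoms$atom_name[blank])
  rownames(atoms) <- NULL
  ensemble(atoms, coords, source_path = path)
}

.format_atom_name <- function(name) {
  # names of up to 3 characters start in column 14 per PDB convention
  ifelse(nchar(name) >= 4L, substr(name, 1, 4),
         sprintf(" %-3s", name))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits one `MODEL`/`ENDMDL` block per frame with fixed-width `ATOM`
#' records (coordinates to 0.001 Angstrom).  Output bytes are a pure
#' function of the ensemble, so identical ensembles give identical files.
#'
#' @param ens an [ensemble()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "Ensemble"))
  at <- ens$atoms
  if (any(at$resnum < 1L)) stop("residue numbers must be >= 1")
  if (any(at$resnum > 9999L)) stop("residue numbers exceed PDB field width")
  name_f <- .format_atom_name(at$atom_name)
  serial <- seq_len(nrow(at))
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character(0)
  for (m in seq_len(ens$frame_count)) {
    xyz <- ens$coords[, , m, drop = FALSE]
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name_f, at$resname, at$chain, at$resnum,
      xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1], 1, 0,
      formatC(at$element, width = 2, flag = " ")
    )
    out <- c(out, sprintf("MODEL     %4d", m), lines, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con, sep = "\n")
  invisible(path)
}
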