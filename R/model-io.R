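#' Atomic model tables
#'
#' Atomic models are ordered tibbles with one row per atom and columns
#' `serial`, `name`, `altloc`, `res_name`, `chain`, `res_seq`, `insert`,
#' `x`, `y`, `z` (Angstrom, map frame), `occupancy`, `bfactor` (ADP, A^2),
#' `element` and `is_hetero`.  Row order follows the source file.  Models
#' read from PDB keep the raw file lines as attributes so that score-labeled
#' copies can be written with every non-occupancy column byte-identical to
#' the input.
#'
#' @param atoms A data frame with at least `name`, `res_name`, `chain`,
#'   `res_seq`, `x`, `y`, `z`, `element`; missing bookkeeping columns are
#'   filled with defaults.
#' @return A tibble of class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) < 1L) stop("a model must contain at least one atom", call. = FALSE)
  need <- c("name", "res_name", "chain", "res_seq", "x", "y", "z", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  defaults <- list(serial = seq_len(nrow(atoms)), altloc = "", insert = "",
                   occupancy = 1, bfactor = 0, is_hetero = FALSE)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  ord <- c("serial", "name", "altloc", "res_name", "chain", "res_seq", "insert",
           "x", "y", "z", "occupancy", "bfactor", "element", "is_hetero")
  atoms <- atoms[, c(ord, setdiff(names(atoms), ord))]
  class(atoms) <- c("atomic_model", class(tibble::tibble()))
  atoms
}

# Element from the atom name per PDB v3.3 conventions, used when the element
# column is blank.  Leading digits are stripped (e.g. "1HB" -> H); a leading
# two-letter match against known species wins only for 4-character or
# heteroatom-style names, otherwise the first letter is the element.
infer_element <- function(name, two_letter_ok = FALSE) {
  two <- c("FE", "MG", "ZN", "CL", "NA", "CA", "MN", "CU", "NI", "CO", "BR", "SE")
  two_letter_ok <- rep_len(two_letter_ok, length(name))
  vapply(seq_along(name), function(i) {
    nm <- gsub("[^A-Za-z]", "", toupper(name[i]))
    if (!nchar(nm)) return("C")
    if (grepl("^[0-9]", toupper(name[i])) || substr(nm, 1, 1) == "H") return("H")
    if (two_letter_ok[i] && nchar(nm) >= 2 && substr(nm, 1, 2) %in% two) {
      return(paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2))))
    }
    substr(nm, 1, 1)
  }, character(1))
}

# Keep one altloc per atom position: highest occupancy, ties -> first seen.
resolve_altlocs <- function(atoms) {
  alt <- ifelse(is.na(atoms$altloc), "", atoms$altloc)
  if (all(alt == "")) return(rep(TRUE, nrow(atoms)))
  key <- paste(atoms$chain, atoms$res_seq, atoms$insert, atoms$res_name,
               atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (grp in split(seq_len(nrow(atoms)), key)) {
    if (length(grp) > 1L && any(alt[grp] != "")) {
      best <- grp[which.max(atoms$occupancy[grp])]
      keep[setdiff(grp, best)] <- FALSE
    }
  }
  keep
}

#' Read an atomic model from PDB or mmCIF
#'
#' All ATOM/HETATM records are retained in file order.  Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first).  Blank
#' element fields are inferred from the atom name.  Hydrogens are kept as
#' deposited.  For PDB input the raw lines are carried along so that
#' [write_labeled_model()] can reproduce the file byte-for-byte outside the
#' occupancy column.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return An [atomic_model] tibble; attributes `source_format`, and for PDB
#'   `pdb_lines` + `atom_line_idx` (line number of each retained atom).
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE,
                                     multi = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE,
                                     multi = FALSE))
  }
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms found in ", path, call. = FALSE)
  elem <- trimws(ifelse(is.na(a$elesy), "", a$elesy))
  blank <- elem == ""
  if (any(blank)) {
    elem[blank] <- infer_element(a$elety[blank], two_letter_ok = a$type[blank] == "HETATM")
  }
  elem <- ifelse(nchar(elem) == 1, toupper(elem),
                 paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2))))
  atoms <- tibble::tibble(
    serial = a$eleno,
    name = trimws(a$elety),
    altloc = trimws(ifelse(is.na(a$alt), "", a$alt)),
    res_name = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "", a$chain),
    res_seq = a$resno,
    insert = trimws(ifelse(is.na(a$insert), "", a$insert)),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    element = elem,
    is_hetero = a$type == "HETATM"
  )
  keep <- resolve_altlocs(atoms)

  lines <- NULL
  line_idx <- NULL
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    cand <- which(grepl("^(ATOM  |HETATM)", lines))
    # bio3d drops records outside the first MODEL; align by count
    if (length(cand) >= nrow(atoms)) line_idx <- cand[seq_len(nrow(atoms))][keep]
  }
  model <- atomic_model(atoms[keep, , drop = FALSE])
  attr(model, "source_format") <- format
  attr(model, "pdb_lines") <- lines
  attr(model, "atom_line_idx") <- line_idx
  model
}

format_pdb_atom_name <- function(name, element) {
  # names starting at column 14 when the element is a single letter and the
  # name has <4 characters; otherwise the name fills columns 13-16
  out <- character(length(name))
  for (i in seq_along(name)) {
    if (nchar(name[i]) < 4 && nchar(element[i]) == 1) {
      out[i] <- sprintf(" %-3s", name[i])
    } else {
      out[i] <- sprintf("%-4s", name[i])
    }
  }
  out
}

model_to_pdb_lines <- function(model, occ = model$occupancy) {
  rec <- ifelse(model$is_hetero, "HETATM", "ATOM  ")
  sprintf(
    "%s%5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, model$serial %% 100000L,
    format_pdb_atom_name(model$name, model$element),
    substr(model$altloc, 1, 1), sprintf("%-3s", model$res_name),
    substr(paste0(model$chain, " "), 1, 1), model$res_seq %% 10000L,
    substr(paste0(model$insert, " "), 1, 1),
    model$x, model$y, model$z, occ, model$bfactor, toupper(model$element)
  )
}

#' Write a score-labeled copy of a model
#'
#' Writes the model as PDB with per-atom scores in the occupancy column
#' (fixed columns 55-60, `%6.2f`), the convention used to colour models by
#' local fit quality in molecular viewers.  Scores outside `[-9.99, 99.99]`
#' are clamped with a warning (format constraint of the fixed-width field).
#' For models read from PDB, every byte outside the occupancy column of the
#' retained atom records is identical to the input.
#'
#' @param model An [atomic_model].
#' @param scores Numeric vector, one score per atom; `NaN`/`NA` allowed and
#'   written as the clamp minimum with a warning.
#' @param path Output path (PDB).
#' @return Invisibly `path`.
#' @export
write_labeled_model <- function(model, scores, path) {
  stopifnot(inherits(model, "atomic_model"))
  if (length(scores) != nrow(model)) {
    stop(sprintf("scores length (%d) != atom count (%d)",
                 length(scores), nrow(model)), call. = FALSE)
  }
  scores <- as.numeric(scores)
  bad <- !is.finite(scores)
  if (any(bad)) {
    warning(sprintf("%d undefined scores written as %.2f", sum(bad), -9.99))
    scores[bad] <- -9.99
  }
  out_of_range <- scores < -9.99 | scores > 99.99
  if (any(out_of_range)) {
    warning(sprintf("%d scores clamped to the PDB occupancy field range [-9.99, 99.99]",
                    sum(out_of_range)))
    scores <- pmin(pmax(scores, -9.99), 99.99)
  }
  occ_field <- sprintf("%6.2f", scores)

  lines <- attr(model, "pdb_lines")
  idx <- attr(model, "atom_line_idx")
  if (!is.null(lines) && !is.null(idx) && length(idx) == nrow(model)) {
    drop <- setdiff(which(grepl("^(ATOM  |HETATM)", lines)), idx)
    for (i in seq_along(idx)) {
      ln <- lines[idx[i]]
      if (nchar(ln) < 60) ln <- sprintf("%-60s", ln)
      substr(ln, 55, 60) <- occ_field[i]
      lines[idx[i]] <- ln
    }
    if (length(drop)) lines <- lines[-drop]  # unselected altloc conformers
    writeLines(lines, path)
  } else {
    writeLines(c(model_to_pdb_lines(model, occ = scores), "END"), path)
  }
  invisible(path)
}
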