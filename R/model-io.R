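## Structure input/output and atom selections.
##
## A MolecularModel is a light S3 container: an ordered atom table
## (author numbering, Angstrom coordinates) plus inferred covalent bonds.
## Parsing of PDB/mmCIF goes through bio3d; the fixed-column PDB writer is
## local so that bead-per-residue toy models round-trip exactly.

PROTEIN_RES <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                 "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
                 "MSE","SEC","PYL")
DNA_RES <- c("DA","DC","DG","DT","DI","DU")
RNA_RES <- c("A","C","G","U","I")

#' Classify a residue name into a molecule class
#'
#' @param resname character vector of 3-letter / nucleotide residue codes.
#' @return character vector with values `"protein"`, `"dna"`, `"rna"` or
#'   `"other"`.
#' @export
molecule_class <- function(resname) {
  rn <- toupper(trimws(resname))
  out <- rep("other", length(rn))
  out[rn %in% PROTEIN_RES] <- "protein"
  out[rn %in% DNA_RES] <- "dna"
  out[rn %in% RNA_RES] <- "rna"
  out
}

#' Construct a molecular model
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `resname`,
#'   `resno`, `ins`, `chain`, `x`, `y`, `z` and optionally `class`
#'   (molecule class; inferred from `resname` when missing). Coordinates are
#'   in Angstrom, residue numbers are the author numbering of the source
#'   file.
#' @param bonds two-column integer matrix of covalent bonds (atom indices
#'   into `atoms`); inferred geometrically when `NULL`.
#' @param title free-text title.
#' @return an object of class `mol_model`.
#' @export
mol_model <- function(atoms, bonds = NULL, title = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "elem", "resname", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$class)) atoms$class <- molecule_class(atoms$resname)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain/residue/name): ", key[duplicated(key)][1])
  rownames(atoms) <- NULL
  m <- structure(list(atoms = atoms, bonds = NULL, title = title),
                 class = "mol_model")
  m$bonds <- if (is.null(bonds)) infer_bonds(m) else {
    b <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(b) && (min(b) < 1L || max(b) > nrow(atoms)))
      stop("bond indices out of range")
    b
  }
  m
}

#' @export
print.mol_model <- function(x, ...) {
  cat(sprintf("<mol_model> %d atoms, %d bonds, %d chains%s\n",
              nrow(x$atoms), nrow(x$bonds), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(" | ", x$title) else ""))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `mol_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinates of a model
#' @param model a `mol_model`.
#' @param unit `"A"` (Angstrom, default) or `"nm"`.
#' @return numeric n x 3 matrix.
#' @export
coords <- function(model, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  xyz <- cbind(model$atoms$x, model$atoms$y, model$atoms$z)
  if (unit == "nm") xyz / A_PER_NM else xyz
}

## ---- covalent bond inference -------------------------------------------

## Heavy-atom geometric bonding: pairs within one residue closer than an
## element-dependent threshold, plus the standard inter-residue linkages
## (peptide C-N, nucleic O3'-P). Residues carrying no linkage atoms at all
## (single-bead models) are chained through their closest atom pair.
infer_bonds <- function(model) {
  at <- model$atoms
  n <- nrow(at)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  heavy_cut <- function(e1, e2) {
    big <- c("S", "P", "SE", "CL", "BR", "FE", "ZN", "MG")
    ifelse(toupper(e1) %in% big | toupper(e2) %in% big, 2.3, 1.85)
  }
  res_id <- paste(at$chain, at$resno, at$ins, sep = "|")
  res_rle <- rle(res_id)
  ends <- cumsum(res_rle$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  bonds <- list()
  add <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(min(i, j), max(i, j))
  xyz <- coords(model)
  dist1 <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  for (r in seq_along(starts)) {
    idx <- starts[r]:ends[r]
    if (length(idx) > 1) {
      d <- as.matrix(stats::dist(xyz[idx, , drop = FALSE]))
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b && d[a, b] < heavy_cut(at$elem[idx[a]], at$elem[idx[b]]))
          add(idx[a], idx[b])
      }
    }
  }
  ## inter-residue backbone linkage between file-consecutive residues
  for (r in seq_len(length(starts) - 1)) {
    i1 <- starts[r]:ends[r]; i2 <- starts[r + 1]:ends[r + 1]
    if (at$chain[i1[1]] != at$chain[i2[1]]) next
    dres <- at$resno[i2[1]] - at$resno[i1[1]]
    if (!(dres %in% c(0L, 1L))) next
    c_i <- i1[at$name[i1] == "C"]; n_j <- i2[at$name[i2] == "N"]
    o3 <- i1[at$name[i1] == "O3'"]; p_j <- i2[at$name[i2] == "P"]
    if (length(c_i) && length(n_j) && dist1(c_i[1], n_j[1]) < 2.0) {
      add(c_i[1], n_j[1])
    } else if (length(o3) && length(p_j) && dist1(o3[1], p_j[1]) < 2.2) {
      add(o3[1], p_j[1])
    } else if (!length(c_i) && !length(o3) && !length(n_j) && !length(p_j)) {
      ## bead-like residues: chain through closest pair
      dmin <- Inf; best <- NULL
      for (a in i1) for (b in i2) {
        d <- dist1(a, b); if (d < dmin) { dmin <- d; best <- c(a, b) }
      }
      if (dmin < 5.0) add(best[1], best[2])
    }
  }
  if (!length(bonds)) return(matrix(integer(0), ncol = 2))
  b <- unique(do.call(rbind, bonds))
  matrix(as.integer(b), ncol = 2)
}

## ---- reading / writing --------------------------------------------------

#' Read a macromolecular structure
#'
#' Parses PDB or mmCIF coordinates into a [mol_model()]. Hydrogens are
#' dropped (the downstream structure-based models are heavy-atom models);
#' for alternate locations only altloc `'A'` or blank is kept and the number
#' of dropped records is reported via a message.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @param format `"auto"` (from extension), `"pdb"` or `"mmcif"`.
#' @return a `mol_model` with atoms in file order and inferred covalent
#'   bonds.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- gsub("[^A-Za-z].*", "", gsub("^[0-9]*", "", at$elety))
  elem <- toupper(trimws(elem))
  guess <- substr(gsub("^[0-9]*", "", trimws(at$elety)), 1, 1)
  elem[!nzchar(elem) | is.na(elem)] <- guess[!nzchar(elem) | is.na(elem)]
  alt <- at$alt; alt[is.na(alt)] <- ""
  keep_alt <- alt %in% c("", "A")
  n_alt_dropped <- sum(!keep_alt)
  keep_h <- !(elem %in% c("H", "D"))
  keep <- keep_alt & keep_h
  if (n_alt_dropped > 0)
    message("read_structure: dropped ", n_alt_dropped, " non-'A' altloc records")
  ins <- at$insert; ins[is.na(ins)] <- ""
  atoms <- data.frame(
    serial = as.integer(at$eleno[keep]),
    name = trimws(at$elety[keep]),
    elem = elem[keep],
    resname = trimws(at$resid[keep]),
    resno = as.integer(at$resno[keep]),
    ins = ins[keep],
    chain = as.character(at$chain[keep]),
    x = as.numeric(at$x[keep]), y = as.numeric(at$y[keep]),
    z = as.numeric(at$z[keep]),
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  unknown <- unique(atoms$resname[molecule_class(atoms$resname) == "other"])
  unknown <- setdiff(unknown, c("HOH", "WAT"))
  if (length(unknown))
    message("read_structure: residues without template treated as class 'other': ",
            paste(unknown, collapse = ", "))
  mol_model(atoms, title = basename(path))
}

#' Write a model as fixed-column PDB
#'
#' @param model a `mol_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  recname <- ifelse(at$class == "other", "HETATM", "ATOM  ")
  aname <- vapply(seq_len(nrow(at)), function(i) {
    nm <- at$name[i]
    if (nchar(nm) >= 4) substr(nm, 1, 4)
    else if (nchar(at$elem[i]) == 2) sprintf("%-4s", nm)
    else sprintf(" %-3s", nm)
  }, character(1))
  lines <- sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   recname, at$serial %% 100000L, aname, substr(at$resname, 1, 3),
                   substr(at$chain, 1, 1), at$resno %% 10000L, at$ins,
                   at$x, at$y, at$z, 1, 0, at$elem)
  header <- if (nzchar(model$title)) sprintf("TITLE     %s", model$title) else NULL
  writeLines(c(header, lines, "END"), path)
  invisible(path)
}

## ---- selections ---------------------------------------------------------

#' Define a selection term: a chain + inclusive residue range
#'
#' @param chain chain identifier.
#' @param start,end inclusive residue-number bounds (author numbering);
#'   `end` defaults to `start`. Use `-Inf`/`Inf` for open ends.
#' @param atom optional atom-name glob (e.g. `"C1'"`, `"C*"`); `NA` keeps all.
#' @return one-row data.frame usable inside [selection_spec()].
#' @export
sel_range <- function(chain, start = -Inf, end = Inf, atom = NA_character_) {
  data.frame(chain = as.character(chain), start = as.numeric(start),
             end = as.numeric(end), atom = as.character(atom),
             stringsAsFactors = FALSE)
}

#' Named groups of selection terms
#'
#' Groups are named lists of [sel_range()] terms (rbind-ed data.frames);
#' residue ranges are inclusive on both ends and use the file's author
#' numbering. Ranges never span insertion codes.
#'
#' @param ... named arguments, each a data.frame of selection terms.
#' @return an object of class `selection_spec`.
#' @export
selection_spec <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.null(names(groups)) && is.list(groups[[1]]) &&
      !is.data.frame(groups[[1]]))
    groups <- groups[[1]]
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("all selection groups must be named")
  for (g in names(groups)) {
    df <- groups[[g]]
    if (!is.data.frame(df) || !all(c("chain", "start", "end") %in% names(df)))
      stop("group '", g, "' is not a data.frame of sel_range() terms")
    if (is.null(df$atom)) groups[[g]]$atom <- NA_character_
  }
  structure(list(groups = groups), class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  cat("<selection_spec>", length(x$groups), "groups:",
      paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

glob_match <- function(glob, x) {
  if (is.na(glob)) rep(TRUE, length(x))
  else grepl(paste0("^", gsub("\\*", ".*", gsub("([.\\\\+^$(){}\\[\\]|?])", "\\\\\\1", glob)), "$"), x)
}

#' Logical membership of model atoms in a selection group
#'
#' @param model a `mol_model`.
#' @param spec a [selection_spec()].
#' @param group group name.
#' @return logical vector over atoms.
#' @export
atoms_in_group <- function(model, spec, group) {
  if (!group %in% names(spec$groups))
    stop("no such selection group: ", group)
  terms <- spec$groups[[group]]
  at <- model$atoms
  absent <- setdiff(unique(terms$chain), unique(at$chain))
  if (length(absent))
    stop("selection group '", group, "' references chain(s) absent from model: ",
         paste(absent, collapse = ", "))
  keep <- rep(FALSE, nrow(at))
  for (r in seq_len(nrow(terms))) {
    hit <- at$chain == terms$chain[r] &
      at$resno >= terms$start[r] & at$resno <= terms$end[r] &
      glob_match(terms$atom[r], at$name)
    keep <- keep | hit
  }
  keep
}

#' Subset a model by a named selection group
#'
#' Preserves atom order; an empty result is legal but reported with a
#' warning.
#'
#' @inheritParams atoms_in_group
#' @return a `mol_model` containing the selected atoms (bonds restricted to
#'   the selection).
#' @export
select_atoms <- function(model, spec, group) {
  keep <- atoms_in_group(model, spec, group)
  if (!any(keep)) warning("selection group '", group, "' matched no atoms")
  idx <- which(keep)
  map <- integer(nrow(model$atoms)); map[idx] <- seq_along(idx)
  b <- model$bonds
  bkeep <- b[keep[b[, 1]] & keep[b[, 2]], , drop = FALSE]
  bnew <- cbind(map[bkeep[, 1]], map[bkeep[, 2]])
  mol_model(model$atoms[idx, , drop = FALSE], bonds = bnew, title = model$title)
}
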