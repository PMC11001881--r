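## Shadow contact maps.
##
## A native contact is an atom pair within `cutoff` whose line of sight is
## not occluded by a third atom, modeled as an opaque sphere of radius
## `shadow_radius` (the light ray itself also carries radius
## `shadow_radius`, so the effective occlusion distance from the segment is
## twice that). Sequence separation is counted in residues within one
## chain; inter-chain pairs are always allowed subject to occlusion.

#' Compute a shadow contact map
#'
#' @param model a [mol_model()].
#' @param cutoff maximum native contact distance, nm (default 0.6 nm = 6 A).
#' @param shadow_radius screening sphere radius, nm (default 0.1 nm = 1 A).
#' @param min_seq_sep_protein minimum residue separation for
#'   protein-protein pairs within a chain (default 3).
#' @param min_seq_sep_nucleic minimum residue separation for pairs
#'   involving nucleic-acid (or other) atoms (default 0).
#' @return object of class `contact_map`: `contacts` data.frame
#'   (`i`, `j`, `r0` in nm, `category`, `group_i`, `group_j`), the
#'   parameters used, and the per-atom metadata needed for classification.
#' @export
shadow_contact_map <- function(model, cutoff = 0.6, shadow_radius = 0.1,
                               min_seq_sep_protein = 3L,
                               min_seq_sep_nucleic = 0L) {
  stopifnot(inherits(model, "mol_model"), cutoff > 0, shadow_radius >= 0)
  if (n_atoms(model) == 0) stop("empty model")
  at <- model$atoms
  classcode <- match(at$class, c("protein", "dna", "rna", "other"))
  classcode <- ifelse(classcode == 1L, 0L, ifelse(classcode %in% c(2L, 3L), 1L, 2L))
  excl <- graph_pairs_within(model$bonds, nrow(at), k = 2L)
  pairs <- shadow_pairs_cpp(coords(model, "nm"), cutoff, shadow_radius,
                            as.integer(factor(at$chain)), as.integer(at$resno),
                            as.integer(classcode), excl,
                            as.integer(min_seq_sep_protein),
                            as.integer(min_seq_sep_nucleic))
  catname <- function(ci, cj) {
    nuc <- function(cc) cc %in% c("dna", "rna", "other")
    ifelse(ci == "protein" & cj == "protein", "protein-protein",
           ifelse(nuc(ci) & nuc(cj), "nucleic-nucleic", "protein-nucleic"))
  }
  i <- as.integer(pairs[, 1]); j <- as.integer(pairs[, 2])
  contacts <- data.frame(
    i = i, j = j, r0 = pairs[, 3],
    category = if (length(i)) catname(at$class[i], at$class[j]) else character(0),
    group_i = rep(NA_character_, length(i)),
    group_j = rep(NA_character_, length(i)),
    stringsAsFactors = FALSE)
  structure(list(contacts = contacts,
                 params = list(cutoff = cutoff, shadow_radius = shadow_radius,
                               min_seq_sep_protein = min_seq_sep_protein,
                               min_seq_sep_nucleic = min_seq_sep_nucleic),
                 atoms = at[, c("name", "resname", "resno", "ins", "chain", "class")],
                 n_atoms = nrow(at)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d contacts over %d atoms (cutoff %.2f nm, shadow %.2f nm)\n",
              nrow(x$contacts), x$n_atoms, x$params$cutoff, x$params$shadow_radius))
  if (nrow(x$contacts)) print(table(x$contacts$category))
  invisible(x)
}

#' Label contacts with selection-group membership
#'
#' Each atom must belong to at most one group of `spec`; contacts are
#' annotated with the pair of group labels of their endpoints (`NA` when an
#' endpoint is outside every group).
#'
#' @param map a [shadow_contact_map()] result.
#' @param spec a [selection_spec()] whose groups partition atoms of
#'   interest (e.g. `NGN`, `KOW`).
#' @param model the model the map was built on.
#' @return the map with `group_i`/`group_j` filled in.
#' @export
classify_contacts <- function(map, spec, model) {
  stopifnot(inherits(map, "contact_map"), inherits(spec, "selection_spec"))
  memb <- rep(NA_character_, map$n_atoms)
  for (g in names(spec$groups)) {
    hit <- atoms_in_group(model, spec, g)
    clash <- hit & !is.na(memb)
    if (any(clash))
      stop("atom in two selection groups: ", memb[which(clash)[1]], " and ", g,
           " (atom ", which(clash)[1], ")")
    memb[hit] <- g
  }
  map$contacts$group_i <- memb[map$contacts$i]
  map$contacts$group_j <- memb[map$contacts$j]
  map
}

#' Contacts spanning two groups
#'
#' @param map a classified `contact_map`.
#' @param group_a,group_b group labels; the interdomain (ID) subset of a
#'   fold-switch model is `contacts_between(map, "NGN", "KOW")`.
#' @return data.frame subset of `map$contacts`.
#' @export
contacts_between <- function(map, group_a, group_b) {
  ct <- map$contacts
  keep <- (!is.na(ct$group_i) & !is.na(ct$group_j)) &
    ((ct$group_i == group_a & ct$group_j == group_b) |
     (ct$group_i == group_b & ct$group_j == group_a))
  ct[keep, , drop = FALSE]
}

#' Contacts internal to one group
#' @inheritParams contacts_between
#' @param group group label.
#' @return data.frame subset of `map$contacts`.
#' @export
contacts_within <- function(map, group) {
  ct <- map$contacts
  ct[!is.na(ct$group_i) & !is.na(ct$group_j) &
       ct$group_i == group & ct$group_j == group, , drop = FALSE]
}

#' Serialize a contact map as TSV
#'
#' @param map a `contact_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  ct <- map$contacts
  at <- map$atoms
  out <- data.frame(i = ct$i, j = ct$j,
                    chain_i = at$chain[ct$i], resno_i = at$resno[ct$i],
                    name_i = at$name[ct$i],
                    chain_j = at$chain[ct$j], resno_j = at$resno[ct$j],
                    name_j = at$name[ct$j],
                    r0_nm = ct$r0, category = ct$category,
                    group_i = ct$group_i, group_j = ct$group_j)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
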