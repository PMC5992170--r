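#' Read a PDB coordinate file into a structure model
#'
#' Parses atomic coordinates (via [bio3d::read.pdb()]), resolves
#' alternate locations by keeping the highest-occupancy conformer (ties
#' broken by altloc label, alphabetically first), and classifies each
#' residue as protein, DNA, water or other by standard residue-name
#' sets.
#'
#' @param path Path to a PDB file.
#' @return An object of class `structure_model`: a data frame of atoms
#'   with columns `chain`, `resno`, `resid`, `atom` (atom name),
#'   `element`, `x`, `y`, `z`, `occupancy`, `altloc`, `polymer`.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  elem <- toupper(trimws(a$elesy))
  guess <- !nzchar(elem) | is.na(elem)
  if (any(guess))  # fall back on the first letter of the atom name
    elem[guess] <- substr(gsub("^[0-9]", "", trimws(a$elety[guess])),
                          1L, 1L)
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      atom = trimws(a$elety), element = elem,
                      x = a$x, y = a$y, z = a$z,
                      occupancy = ifelse(is.na(a$o), 1, a$o),
                      altloc = ifelse(is.na(a$alt) | a$alt == "",
                                      "", a$alt),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)

  # altloc resolution: highest occupancy, ties by label
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]

  atoms$polymer <- classify_residue(atoms$resid)
  if (any(atoms$polymer == "other"))
    warning("unknown residue name(s) classified 'other': ",
            paste(unique(atoms$resid[atoms$polymer == "other"]),
                  collapse = ", "))
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$atom), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

PROTEIN_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                      "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                      "PRO", "SER", "THR", "TRP", "TYR", "VAL", "MSE",
                      "SEC", "PYL")
DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "DI", "DU")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

classify_residue <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- rep("other", length(resid))
  out[resid %in% PROTEIN_RESIDUES] <- "protein"
  out[resid %in% DNA_RESIDUES] <- "DNA"
  out[resid %in% WATER_RESIDUES] <- "water"
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure model: ", nrow(x), " atoms\n", sep = "")
  tab <- table(x$polymer)
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
  invisible(x)
}

#' Count non-hydrogen atoms of a polymer class
#'
#' Atom counts after alternate-location resolution, the quantity
#' reported per class (protein / DNA / water) in crystallographic
#' refinement tables.
#'
#' @param model A [read_structure()] model.
#' @param polymer_class One of `"protein"`, `"DNA"`, `"water"`,
#'   `"other"`.
#' @return Integer count.
#' @export
count_atoms <- function(model, polymer_class) {
  stopifnot(inherits(model, "structure_model"))
  if (!polymer_class %in% c("protein", "DNA", "water", "other"))
    stop("unknown polymer class: ", polymer_class, call. = FALSE)
  sum(model$polymer == polymer_class & model$element != "H" &
        model$element != "D")
}

#' Detect hydrogen bonds by donor-acceptor distance
#'
#' Heavy-atom criterion: every nitrogen/oxygen pair from different
#' residues whose distance lies within `(min_dist, cutoff]` is reported
#' as a hydrogen bond. No angle term is applied because crystallographic
#' models at this resolution lack hydrogens; the cutoff is configurable
#' (3.5 Å default; 4.0 Å captures the long threonine-adenine contacts).
#'
#' @param model A `structure_model`.
#' @param cutoff Maximum donor-acceptor distance in Å (default 3.5).
#' @param min_dist Distances at or below this are treated as covalent or
#'   clashing and excluded (default 2.2 Å).
#' @param include_water Include water oxygens (default `FALSE`).
#' @return A data frame with one row per bond: donor/acceptor chain,
#'   residue number, residue name, atom name, and `distance` (Å, to
#'   0.01). The member with the lower (chain, residue) sorts as
#'   "donor" — donor/acceptor roles are not assignable without
#'   hydrogens.
#' @export
find_hbonds <- function(model, cutoff = 3.5, min_dist = 2.2,
                        include_water = FALSE) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  sel <- model$element %in% c("N", "O")
  if (!include_water) sel <- sel & model$polymer != "water"
  at <- model[sel, , drop = FALSE]
  empty <- data.frame(chain1 = character(), resno1 = integer(),
                      resid1 = character(), atom1 = character(),
                      chain2 = character(), resno2 = integer(),
                      resid2 = character(), atom2 = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(at) < 2L) return(empty)
  d <- as.matrix(dist(at[, c("x", "y", "z")]))
  same_res <- outer(paste(at$chain, at$resno),
                    paste(at$chain, at$resno), "==")
  hit <- which(d > min_dist & d <= cutoff & !same_res &
                 upper.tri(d), arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  out <- data.frame(chain1 = at$chain[i], resno1 = at$resno[i],
                    resid1 = at$resid[i], atom1 = at$atom[i],
                    chain2 = at$chain[j], resno2 = at$resno[j],
                    resid2 = at$resid[j], atom2 = at$atom[j],
                    distance = round(d[hit], 2),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain1, out$resno1, out$chain2, out$resno2,
                   out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# side-chain donor/acceptor atom names used in the junction networks
SIDECHAIN_POLAR <- list(ARG = c("NE", "NH1", "NH2"),
                        GLU = c("OE1", "OE2"),
                        LYS = "NZ")

#' Inter-repeat hydrogen-bond junction networks of a PPR solenoid
#'
#' For each junction between consecutive repeats (junction `j` joins
#' repeat `j` to repeat `j+1`), tests the three side-chain contacts that
#' tie the convex-face b helices together: Arg16-Glu19 within repeat
#' `j+1`, Arg16 of repeat `j+1` to Glu18 of repeat `j`, and Lys28 of
#' repeat `j` to Glu26 of repeat `j+1`. Residue numbers come from the
#' cap + 35*(r-1) + p arithmetic of [global_residue_index()]. A contact
#' whose residues are missing (or not Arg/Glu/Lys) is `NA`
#' ("indeterminate"), not silently absent.
#'
#' @param model A `structure_model`.
#' @param n_repeats Number of repeats in the design.
#' @param cap_len N-cap length (default 4).
#' @param chain Chain to analyse (default: the first protein chain).
#' @param cutoff Side-chain N-O distance cutoff in Å (default 3.5).
#' @return A data frame of class `junction_network` with `n_repeats - 1`
#'   rows: `junction`, logical `arg16_glu19`, `arg16_glu18_prev`,
#'   `lys28_glu26`.
#' @export
junction_networks <- function(model, n_repeats, cap_len = 4L,
                              chain = NULL, cutoff = 3.5) {
  stopifnot(inherits(model, "structure_model"), n_repeats >= 2L)
  if (is.null(chain))
    chain <- model$chain[model$polymer == "protein"][1]
  prot <- model[model$chain == chain & model$polymer == "protein", ,
                drop = FALSE]

  side_atoms <- function(resno, resname) {
    r <- prot[prot$resno == resno, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    if (!toupper(r$resid[1]) %in% names(SIDECHAIN_POLAR) ||
        toupper(r$resid[1]) != resname) return(NULL)
    r[r$atom %in% SIDECHAIN_POLAR[[resname]], , drop = FALSE]
  }
  in_contact <- function(a, b) {
    if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b))
      return(NA)
    dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
    dz <- outer(a$z, b$z, "-")
    any(sqrt(dx^2 + dy^2 + dz^2) <= cutoff)
  }

  junctions <- seq_len(n_repeats - 1L)
  res <- lapply(junctions, function(j) {
    r_next <- j + 1L
    arg16 <- side_atoms(global_residue_index(r_next, 16L, cap_len), "ARG")
    glu19 <- side_atoms(global_residue_index(r_next, 19L, cap_len), "GLU")
    glu18p <- side_atoms(global_residue_index(j, 18L, cap_len), "GLU")
    lys28 <- side_atoms(global_residue_index(j, 28L, cap_len), "LYS")
    glu26 <- side_atoms(global_residue_index(r_next, 26L, cap_len), "GLU")
    c(arg16_glu19 = in_contact(arg16, glu19),
      arg16_glu18_prev = in_contact(arg16, glu18p),
      lys28_glu26 = in_contact(lys28, glu26))
  })
  out <- data.frame(junction = junctions,
                    do.call(rbind, res))
  class(out) <- c("junction_network", "data.frame")
  attr(out, "cutoff") <- cutoff
  attr(out, "chain") <- chain
  out
}

#' @export
print.junction_network <- function(x, ...) {
  cat("inter-repeat junction network (chain ", attr(x, "chain"),
      ", cutoff ", attr(x, "cutoff"), " Å)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Count Arg16-Glu19 junctions rearranged between two states
#'
#' A junction is "rearranged" when its within-repeat Arg16-Glu19
#' side-chain bond is present in the apo network and absent in the
#' bound one — the switch that opens the convex face as the solenoid
#' wraps its target. Indeterminate junctions (NA in either state) are
#' excluded from the count and reported.
#'
#' @param apo,bound `junction_network` objects over the same number of
#'   junctions.
#' @return Integer count, with attributes `junctions` (which ones) and
#'   `indeterminate` (excluded junction indices).
#' @export
compare_networks <- function(apo, bound) {
  stopifnot(inherits(apo, "junction_network"),
            inherits(bound, "junction_network"))
  if (nrow(apo) != nrow(bound))
    stop("junction counts differ (", nrow(apo), " vs ", nrow(bound), ")",
         call. = FALSE)
  ind <- is.na(apo$arg16_glu19) | is.na(bound$arg16_glu19)
  rearranged <- !ind & apo$arg16_glu19 & !bound$arg16_glu19
  if (any(ind))
    message("junction(s) ", paste(apo$junction[ind], collapse = ", "),
            " indeterminate; excluded from the comparison")
  structure(sum(rearranged),
            junctions = apo$junction[rearranged],
            indeterminate = apo$junction[ind])
}

#' Superhelix length of a PPR solenoid
#'
#' Measured as the maximum pairwise C-alpha/C-alpha distance over
#' protein atoms — a convention for the end-to-end extent of the
#' solenoid, recorded with the result. Compaction on target binding
#' shows as a decrease in this length.
#'
#' @param model A `structure_model`.
#' @param chain Optional chain restriction.
#' @return Length in Å, with attribute `convention`.
#' @export
superhelix_length <- function(model, chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  ca <- model[model$polymer == "protein" & model$atom == "CA", ,
              drop = FALSE]
  if (!is.null(chain)) ca <- ca[ca$chain == chain, , drop = FALSE]
  if (nrow(ca) < 2L)
    stop("need at least two C-alpha atoms", call. = FALSE)
  len <- max(dist(ca[, c("x", "y", "z")]))
  structure(len, convention = "max pairwise CA-CA distance")
}

#' Fetch a deposited PDB entry (network required)
#'
#' Convenience downloader for deposited coordinate files used as
#' optional validation inputs. Requires internet access; all package
#' computations accept local files, so this is never needed offline.
#'
#' @param accession 4-character PDB accession (e.g. `"5ORM"`).
#' @param dest Destination file (default `<accession>.pdb` in `tempdir()`).
#' @return The path to the downloaded file.
#' @export
fetch_structure <- function(accession,
                            dest = file.path(tempdir(),
                                             paste0(accession, ".pdb"))) {
  url <- paste0("https://files.rcsb.org/download/",
                toupper(accession), ".pdb")
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}
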