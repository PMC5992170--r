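#' Write a synthetic PPR solenoid coordinate file
#'
#' Builds an idealised, deliberately minimal coordinate model of an
#' R-repeat cPPR for exercising the structural metrics without deposited
#' data: one C-alpha per tracked residue laid out along the solenoid
#' axis so that the end-to-end extent is exactly `length_A`, plus the
#' side-chain polar atoms (Arg16 NH1, Glu18/Glu19/Glu26 OE1, Lys28 NZ)
#' placed in or out of hydrogen-bonding distance junction by junction.
#' This is a synthetic stand-in — it has the topology and the tracked
#' contacts of a PPR solenoid, not its full chemistry.
#'
#' @param file Output PDB path.
#' @param n_repeats Number of repeats (default 10).
#' @param length_A End-to-end C-alpha extent in Å.
#' @param arg16_glu19 Logical vector (length `n_repeats - 1`): is the
#'   within-repeat Arg16-Glu19 bond formed at each junction?
#' @param lys28_glu26 Logical vector: is the Lys28-Glu26 cross-repeat
#'   bond formed at each junction?
#' @param cap_len N-cap length used for residue numbering (default 4).
#' @param chain Protein chain id.
#' @param dna_nt Number of DNA nucleotides to add on chain `"B"`
#'   (3 heavy atoms each; 0 for an apo model).
#' @param waters Number of water oxygens to add.
#' @param bond_dist Donor-acceptor distance for formed bonds (default
#'   2.8 Å).
#' @return Invisibly, `file`.
#' @export
synthetic_solenoid <- function(file, n_repeats = 10L, length_A = 104,
                               arg16_glu19 = rep(TRUE, n_repeats - 1L),
                               lys28_glu26 = rep(TRUE, n_repeats - 1L),
                               cap_len = 4L, chain = "A", dna_nt = 0L,
                               waters = 0L, bond_dist = 2.8) {
  stopifnot(length(arg16_glu19) == n_repeats - 1L,
            length(lys28_glu26) == n_repeats - 1L)
  tracked <- c(ARG = 16L, GLU = 18L, GLU2 = 19L, GLU3 = 26L, LYS = 28L)
  resname <- c(ARG = "ARG", GLU = "GLU", GLU2 = "GLU", GLU3 = "GLU",
               LYS = "LYS")
  side <- c(ARG = "NH1", GLU = "OE1", GLU2 = "OE1", GLU3 = "OE1",
            LYS = "NZ")
  side_elem <- c(ARG = "N", GLU = "O", GLU2 = "O", GLU3 = "O", LYS = "N")

  g_all <- unlist(lapply(seq_len(n_repeats), function(r)
    global_residue_index(r, tracked, cap_len)))
  gmin <- min(g_all); gmax <- max(g_all)
  axis_x <- function(g) (g - gmin) / (gmax - gmin) * length_A

  rows <- list(); serial <- 0L
  add <- function(name, elem, resn, ch, resno, x, y, z) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, paste0(" ", name), resn, ch, resno, x, y, z, 1.00, 20.00,
      elem)
  }

  for (r in seq_len(n_repeats)) {
    for (k in names(tracked)) {
      g <- global_residue_index(r, tracked[[k]], cap_len)
      add("CA", "C", resname[[k]], chain, g, axis_x(g), 0, 0)
    }
    # Arg16(r) & Glu19(r): the within-repeat pair governing junction r-1
    x16 <- axis_x(global_residue_index(r, 16L, cap_len))
    formed <- if (r == 1L) TRUE else arg16_glu19[r - 1L]
    add("NH1", "N", "ARG", chain,
        global_residue_index(r, 16L, cap_len), x16, 3, 0)
    add("OE1", "O", "GLU", chain,
        global_residue_index(r, 19L, cap_len),
        x16, if (formed) 3 + bond_dist else 30, 0)
    # Glu18(r): paired with Arg16(r+1) across the junction; kept out of
    # range here (its rearrangement is not the tracked switch)
    add("OE1", "O", "GLU", chain,
        global_residue_index(r, 18L, cap_len),
        axis_x(global_residue_index(r, 18L, cap_len)), -30, 0)
    # Lys28(r) reaches Glu26(r+1) when junction r is formed
    if (r < n_repeats) {
      xj <- axis_x(global_residue_index(r, 28L, cap_len))
      add("NZ", "N", "LYS", chain,
          global_residue_index(r, 28L, cap_len), xj, -3, 8)
      add("OE1", "O", "GLU", chain,
          global_residue_index(r + 1L, 26L, cap_len),
          xj, if (lys28_glu26[r]) -3 - bond_dist else -60, 8)
    } else {
      add("NZ", "N", "LYS", chain,
          global_residue_index(r, 28L, cap_len),
          axis_x(global_residue_index(r, 28L, cap_len)), -3, 8)
    }
  }

  if (dna_nt > 0L) {
    for (i in seq_len(dna_nt)) {
      x <- (i - 1) * 6
      add("P", "P", "DT", "B", i, x, 12, 0)
      add("C1'", "C", "DT", "B", i, x, 13.5, 0)
      add("N1", "N", "DT", "B", i, x, 15, 0)
    }
  }
  if (waters > 0L) {
    for (i in seq_len(waters))
      add("O", "O", "HOH", "S", 500L + i, (i - 1) * 5, 25, 10)
  }

  writeLines(c(unlist(rows), "END"), file)
  invisible(file)
}

#' Write a synthetic apo/bound solenoid pair
#'
#' The apo model has every Arg16-Glu19 and Lys28-Glu26 junction bond
#' formed and an extended solenoid; the bound model loses the
#' Arg16-Glu19 bond at the given junctions, loses every Lys28-Glu26
#' bond (the lysine switches to an intra-repeat partner on binding), is
#' compacted, and carries a DNA chain. Mirrors the qualitative
#' rearrangement a PPR solenoid undergoes on wrapping its ssDNA target.
#'
#' @param dir Output directory.
#' @param n_repeats Number of repeats.
#' @param apo_length,bound_length End-to-end extents in Å.
#' @param rearranged Junction indices whose Arg16-Glu19 bond is lost on
#'   binding.
#' @param dna_nt DNA nucleotides in the bound model.
#' @return List with paths `apo` and `bound`.
#' @export
synthetic_solenoid_pair <- function(dir = tempdir(), n_repeats = 10L,
                                    apo_length = 104, bound_length = 64,
                                    rearranged = c(3L, 5L, 8L),
                                    dna_nt = 10L) {
  nj <- n_repeats - 1L
  apo <- file.path(dir, "synthetic_apo.pdb")
  bound <- file.path(dir, "synthetic_bound.pdb")
  synthetic_solenoid(apo, n_repeats, apo_length,
                     arg16_glu19 = rep(TRUE, nj),
                     lys28_glu26 = rep(TRUE, nj),
                     waters = 8L)
  keep <- !(seq_len(nj) %in% rearranged)
  synthetic_solenoid(bound, n_repeats, bound_length,
                     arg16_glu19 = keep,
                     lys28_glu26 = rep(FALSE, nj),
                     dna_nt = dna_nt, waters = 4L)
  list(apo = apo, bound = bound)
}
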