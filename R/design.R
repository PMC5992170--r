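#' Assemble a cPPR protein against a nucleic-acid target
#'
#' Forward design: one 35-aa consensus repeat per target base, with the
#' residues at repeat positions 5 and 35 substituted according to the
#' base-recognition code, flanked by an N-terminal cap and a C-terminal
#' solvating helix. Repeat 1 (most N-terminal) reads the 5'-most target
#' base, so the repeat order mirrors the 5'->3' target sequence.
#'
#' @param target Nucleotide target, 5'->3', over `A`, `C`, `G`, `T`/`U`
#'   (a plain string or a length-1 [Biostrings::DNAStringSet] element;
#'   `U` is read as `T`).
#' @param name Label for the design.
#' @param template A [repeat_template()].
#' @param n_cap,c_helix Cap sequences. Defaults are the
#'   Met-Gly-Asn-Ser N-cap and the Val-Thr-Tyr-Thr-Thr-Leu-Ile-Ser-Gly-
#'   Leu-Gly-Lys-Ala-Gly solvating helix used in consensus PPR designs.
#' @param code A code table from [ppr_code_table()].
#' @return An object of class `cppr_design`: a list with elements
#'   `name`, `target` (DNA alphabet), `rna` (whether the input used U),
#'   `repeats` (data frame with columns `repeat_`, `base`, `aa5`,
#'   `aa35`, `from`, `to` — global residue range of each repeat),
#'   `n_cap`, `c_helix` and `protein` (full amino-acid sequence).
#' @examples
#' d <- build_design("TTAGGGTTAG", name = "cPPR-Telo1")
#' d
#' nchar(d$protein)  # 4 + 10*35 + 14 = 368
#' @seealso [parse_design()] for the inverse, [homopolymer_design()].
#' @export
build_design <- function(target, name = "cPPR-design",
                         template = repeat_template(),
                         n_cap = "MGNS", c_helix = "VTYTTLISGLGKAG",
                         code = ppr_code_table()) {
  target <- as.character(target)
  if (length(target) != 1L || is.na(target) || !nzchar(target))
    stop("target must be a single non-empty nucleotide string",
         call. = FALSE)
  raw <- toupper(target)
  rna <- grepl("U", raw, fixed = TRUE)
  bases <- strsplit(raw, "")[[1]]
  bases[bases == "U"] <- "T"
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad))
    stop("invalid base symbol(s) in target: ", paste(bad, collapse = ", "),
         call. = FALSE)
  validate_template(template)

  pairs <- t(vapply(bases, residues_for_base, c(aa5 = "", aa35 = ""),
                    code = code))
  tpl <- strsplit(template$sequence, "")[[1]]
  rep_seqs <- vapply(seq_along(bases), function(i) {
    aa <- tpl
    aa[5L] <- pairs[i, "aa5"]
    aa[REPEAT_LEN] <- pairs[i, "aa35"]
    paste(aa, collapse = "")
  }, "")

  cap_len <- nchar(n_cap)
  from <- cap_len + REPEAT_LEN * (seq_along(bases) - 1L) + 1L
  repeats <- data.frame(
    repeat_ = seq_along(bases),
    base = bases,
    aa5 = unname(pairs[, "aa5"]),
    aa35 = unname(pairs[, "aa35"]),
    from = from,
    to = from + REPEAT_LEN - 1L,
    stringsAsFactors = FALSE)

  protein <- paste0(n_cap, paste(rep_seqs, collapse = ""), c_helix)
  stopifnot(nchar(protein) ==
              nchar(n_cap) + REPEAT_LEN * length(bases) + nchar(c_helix))

  structure(list(name = name,
                 target = paste(bases, collapse = ""),
                 rna = rna,
                 repeats = repeats,
                 n_cap = n_cap,
                 c_helix = c_helix,
                 protein = protein),
            class = "cppr_design")
}

#' Design a homopolymer-binding cPPR
#'
#' Convenience wrapper for the classic designs against homopolymeric
#' targets: eight identical repeats all carrying the same specificity
#' pair, e.g. all (T,N) for a poly(A) binder.
#'
#' @param base The base to read at every repeat (`A`, `C`, `G`, `T`/`U`).
#' @param n_repeats Number of repeats; the typical design uses 8.
#' @param ... Passed to [build_design()].
#' @return A `cppr_design`.
#' @examples
#' homopolymer_design("A")  # 8 repeats, all (T,N)
#' @export
homopolymer_design <- function(base, n_repeats = 8L, ...) {
  b <- normalize_base(base)
  if (length(b) != 1L || b == "N")
    stop("base must be a single symbol in A, C, G, T, U", call. = FALSE)
  build_design(strrep(toupper(base), n_repeats),
               name = paste0("cPPR-poly", toupper(base)), ...)
}

#' Map repeat-local residue positions to global residue indices
#'
#' A residue at local position `p` of repeat `r` sits at global index
#' `cap_len + repeat_len*(r-1) + p` in the full protein. This is the
#' arithmetic behind the standardised annotation of PPR motifs: with the
#' 4-residue N-cap and 35-aa repeats, Arg16 of repeat 5 is Arg160 of the
#' protein, Lys28 of repeat 4 is Lys137, Glu19 of repeat 9 is Glu303.
#'
#' @param repeat_ Repeat number, 1-based from the N terminus.
#' @param local_pos Position within the repeat, 1-based, in
#'   `1..repeat_len`.
#' @param cap_len Length of the N-terminal cap (default 4, `MGNS`).
#' @param repeat_len Repeat length (default 35).
#' @return Integer global residue index (vectorised).
#' @examples
#' global_residue_index(5, 16)  # 160
#' global_residue_index(4, 28)  # 137
#' @seealso [local_residue_index()] for the inverse.
#' @export
global_residue_index <- function(repeat_, local_pos, cap_len = 4L,
                                 repeat_len = REPEAT_LEN) {
  repeat_ <- as.integer(repeat_); local_pos <- as.integer(local_pos)
  if (any(repeat_ < 1L))
    stop("repeat_ must be >= 1", call. = FALSE)
  if (any(local_pos < 1L | local_pos > repeat_len))
    stop("local_pos must be in 1..", repeat_len, call. = FALSE)
  cap_len + repeat_len * (repeat_ - 1L) + local_pos
}

#' Map a global residue index back to (repeat, local position)
#'
#' Inverse of [global_residue_index()] over the residue range occupied
#' by the repeats.
#'
#' @param global Global residue index (vectorised).
#' @inheritParams global_residue_index
#' @return A data frame with integer columns `repeat_` and `local_pos`.
#' @examples
#' local_residue_index(160)  # repeat 5, local position 16
#' @export
local_residue_index <- function(global, cap_len = 4L,
                                repeat_len = REPEAT_LEN) {
  global <- as.integer(global)
  if (any(global <= cap_len))
    stop("global index falls in the N-cap, not in a repeat", call. = FALSE)
  off <- global - cap_len - 1L
  data.frame(repeat_ = off %/% repeat_len + 1L,
             local_pos = off %% repeat_len + 1L)
}

#' Recover the predicted target from a cPPR protein sequence
#'
#' Reverse engineering: decompose a protein sequence into cap + repeats +
#' solvating helix, read the residues at positions 5 and 35 of each
#' repeat, and translate them back to bases via the recognition code.
#' Pairs absent from the code table give the wildcard `N`. Non-variable
#' template positions are allowed to deviate from the consensus up to
#' `max_mismatch_frac` of the fixed positions per repeat, so natural or
#' variant PPR sequences can still be parsed.
#'
#' @param protein Amino-acid sequence (string or `cppr_design`).
#' @param template A [repeat_template()].
#' @param n_cap,c_helix Expected cap sequences (their lengths drive the
#'   decomposition).
#' @param code A code table from [ppr_code_table()].
#' @param max_mismatch_frac Maximum tolerated fraction of mismatches at
#'   non-variable template positions, per repeat (default 0.2).
#' @param rna If `TRUE`, report `U` instead of `T` in the prediction.
#' @return The predicted target as a single string over `A`, `C`, `G`,
#'   `T` (or `U`) and `N`.
#' @examples
#' parse_design(build_design("TTAGGGTTAG"))  # "TTAGGGTTAG"
#' @export
parse_design <- function(protein, template = repeat_template(),
                         n_cap = "MGNS", c_helix = "VTYTTLISGLGKAG",
                         code = ppr_code_table(),
                         max_mismatch_frac = 0.2, rna = FALSE) {
  if (inherits(protein, "cppr_design")) protein <- protein$protein
  protein <- toupper(as.character(protein))
  if (length(protein) != 1L || !nzchar(protein))
    stop("protein must be a single non-empty amino-acid string",
         call. = FALSE)
  core <- nchar(protein) - nchar(n_cap) - nchar(c_helix)
  if (core < REPEAT_LEN || core %% REPEAT_LEN != 0L)
    stop("protein length ", nchar(protein), " does not decompose into ",
         "cap (", nchar(n_cap), ") + 35*R + helix (", nchar(c_helix),
         "); residual of ",
         if (core < REPEAT_LEN) core else core %% REPEAT_LEN,
         " residues", call. = FALSE)
  n_rep <- core %/% REPEAT_LEN
  tpl <- strsplit(template$sequence, "")[[1]]
  fixed_pos <- setdiff(seq_len(REPEAT_LEN), template$variable_positions)
  max_mm <- floor(max_mismatch_frac * length(fixed_pos))

  bases <- character(n_rep)
  for (r in seq_len(n_rep)) {
    start <- nchar(n_cap) + REPEAT_LEN * (r - 1L) + 1L
    aa <- strsplit(substr(protein, start, start + REPEAT_LEN - 1L), "")[[1]]
    mm <- sum(aa[fixed_pos] != tpl[fixed_pos])
    if (mm > max_mm)
      stop("repeat ", r, " deviates from the consensus template at ", mm,
           " fixed positions (tolerance ", max_mm, ")", call. = FALSE)
    b <- base_for_residues(aa[5L], aa[REPEAT_LEN], code = code)
    bases[r] <- b
  }
  if (rna) bases[bases == "T"] <- "U"
  paste(bases, collapse = "")
}

#' @export
print.cppr_design <- function(x, ...) {
  cat("cPPR design:", x$name, "\n")
  cat("  target (5'->3'):", if (x$rna) gsub("T", "U", x$target) else
    x$target, "\n")
  cat("  repeats: ", nrow(x$repeats), " (", REPEAT_LEN, " aa each)\n",
      sep = "")
  cat("  specificity pairs:",
      paste0(x$repeats$aa5, x$repeats$aa35, collapse = " "), "\n")
  cat("  protein:", nchar(x$protein), "aa =",
      nchar(x$n_cap), "(cap) +", nrow(x$repeats), "x", REPEAT_LEN,
      "+", nchar(x$c_helix), "(helix)\n")
  invisible(x)
}

#' Write a design to FASTA with a JSON sidecar
#'
#' The protein sequence goes to FASTA; the design metadata (target,
#' per-repeat specificity pairs and global residue ranges, caps) goes to
#' `<fasta>.json`.
#'
#' @param design A `cppr_design`.
#' @param fasta Output FASTA path.
#' @param json Output JSON path (default `<fasta>.json`).
#' @return Invisibly, the two paths.
#' @export
write_design <- function(design, fasta,
                         json = paste0(fasta, ".json")) {
  stopifnot(inherits(design, "cppr_design"))
  seqs <- Biostrings::AAStringSet(setNames(design$protein, design$name))
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- list(name = design$name, target = design$target,
               rna = design$rna, n_cap = design$n_cap,
               c_helix = design$c_helix, repeats = design$repeats)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, json = json))
}

#' Read a nucleotide target from FASTA or a literal string
#'
#' @param x A path to a FASTA file (first record used) or a literal
#'   nucleotide string.
#' @return A single uppercase nucleotide string.
#' @export
read_target <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    if (!length(ss)) stop("no sequences in ", x, call. = FALSE)
    return(toupper(as.character(ss[[1]])))
  }
  toupper(as.character(x))
}
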