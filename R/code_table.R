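#' The modular PPR base-recognition code
#'
#' Amino acids at positions 5 and 35 of each PPR repeat determine which
#' nucleotide base the repeat recognises. The canonical code has four
#' entries: (T,N) reads A, (T,D) reads G, (N,D) reads T (or U in RNA) and
#' (N,S) reads C. The table is data, not hard-coded: extended codes from
#' the literature can be supplied as a tab-separated file with columns
#' `aa5`, `aa35`, `base`.
#'
#' U and T are treated as the same base internally (the code does not
#' distinguish them; the same residue pairs bind both RNA and ssDNA), so
#' tables may list either symbol and lookups accept either.
#'
#' @param file Path to a tab-separated code table. The default is the
#'   canonical four-entry table shipped with the package.
#' @return A data frame of class `ppr_code` with character columns `aa5`,
#'   `aa35`, `base`.
#' @examples
#' ppr_code_table()
#' @export
ppr_code_table <- function(file = system.file("extdata", "ppr_code.tsv",
                                              package = "pprkit")) {
  tab <- read.delim(file, header = TRUE, colClasses = "character")
  required <- c("aa5", "aa35", "base")
  if (!all(required %in% names(tab)))
    stop("code table must have columns aa5, aa35, base", call. = FALSE)
  tab$aa5 <- toupper(trimws(tab$aa5))
  tab$aa35 <- toupper(trimws(tab$aa35))
  tab$base <- normalize_base(tab$base)
  validate_code_table(tab)
  class(tab) <- c("ppr_code", "data.frame")
  tab
}

# A loaded table must contain the four canonical entries and must not map
# one residue pair to two different bases.
validate_code_table <- function(tab) {
  if (!all(tab$aa5 %in% AA1) || !all(tab$aa35 %in% AA1))
    stop("code table contains non-amino-acid one-letter codes", call. = FALSE)
  key <- paste(tab$aa5, tab$aa35)
  dup <- key[duplicated(key)]
  conflicting <- vapply(unique(dup), function(k) {
    length(unique(tab$base[key == k])) > 1L
  }, logical(1))
  if (any(conflicting))
    stop("code table is not injective: residue pair(s) ",
         paste(unique(dup)[conflicting], collapse = ", "),
         " map to more than one base", call. = FALSE)
  canon <- data.frame(aa5 = c("T", "T", "N", "N"),
                      aa35 = c("N", "D", "D", "S"),
                      base = c("A", "G", "T", "C"))
  for (i in seq_len(nrow(canon))) {
    hit <- tab$aa5 == canon$aa5[i] & tab$aa35 == canon$aa35[i]
    if (!any(hit) || tab$base[which(hit)[1]] != canon$base[i])
      stop("code table is missing canonical entry (",
           canon$aa5[i], ",", canon$aa35[i], ") -> ", canon$base[i],
           call. = FALSE)
  }
  invisible(tab)
}

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Collapse U onto T and validate base symbols.
normalize_base <- function(base) {
  base <- toupper(trimws(base))
  base[base == "U"] <- "T"
  bad <- setdiff(unique(base), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("unknown base symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  base
}

#' Look up the residue pair that recognises a base
#'
#' Forward direction of the PPR code: which amino acids at repeat
#' positions 5 and 35 program a repeat to read the given base.
#'
#' @param base A single base symbol, one of `A`, `C`, `G`, `T` or `U`
#'   (`U` is treated as `T`).
#' @param code A code table from [ppr_code_table()].
#' @return A named character vector `c(aa5 = , aa35 = )`.
#' @examples
#' residues_for_base("A")  # c(aa5 = "T", aa35 = "N")
#' residues_for_base("G")  # c(aa5 = "T", aa35 = "D")
#' @export
residues_for_base <- function(base, code = ppr_code_table()) {
  if (length(base) != 1L || !is.character(base))
    stop("base must be a single character", call. = FALSE)
  b <- normalize_base(base)
  hit <- which(code$base == b)
  if (!length(hit))
    stop("no code-table entry for base ", base, call. = FALSE)
  # canonical pair: the first entry listed for that base
  c(aa5 = code$aa5[hit[1]], aa35 = code$aa35[hit[1]])
}

#' Look up the base recognised by a residue pair
#'
#' Inverse direction of the PPR code. Residue pairs absent from the table
#' return the wildcard `N` rather than an error, so natural PPR sequences
#' carrying non-canonical codes can still be read.
#'
#' @param aa5,aa35 Single one-letter amino-acid codes at repeat positions
#'   5 and 35.
#' @inheritParams residues_for_base
#' @return A single base (`A`, `C`, `G`, `T`) or `N` if the pair is not
#'   in the table.
#' @examples
#' base_for_residues("T", "N")  # "A"
#' base_for_residues("A", "A")  # "N" (non-canonical pair)
#' @export
base_for_residues <- function(aa5, aa35, code = ppr_code_table()) {
  aa5 <- toupper(aa5); aa35 <- toupper(aa35)
  if (length(aa5) != 1L || length(aa35) != 1L ||
      !aa5 %in% AA1 || !aa35 %in% AA1)
    stop("aa5 and aa35 must be single one-letter amino-acid codes",
         call. = FALSE)
  hit <- which(code$aa5 == aa5 & code$aa35 == aa35)
  if (!length(hit)) return("N")
  code$base[hit[1]]
}

#' @export
print.ppr_code <- function(x, ...) {
  cat("PPR base-recognition code (", nrow(x), " residue pairs)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
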