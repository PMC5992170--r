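#' Bind-n-Seq library construct
#'
#' The selection library is a fixed-flank oligonucleotide with a central
#' randomised insert: 5' flank, `insert_len` random bases, 3' flank. The
#' defaults reproduce the construct
#' `CTTTATCCAGCCCTCAC` + `NNNNNNNNNN` + `CTATAGTGTCACCTAAATC`.
#'
#' @param flank5,flank3 Fixed flanking sequences.
#' @param insert_len Length of the randomised insert (default 10).
#' @return A list of class `library_construct`.
#' @export
library_construct <- function(flank5 = "CTTTATCCAGCCCTCAC",
                              insert_len = 10L,
                              flank3 = "CTATAGTGTCACCTAAATC") {
  flank5 <- normalize_seq(flank5); flank3 <- normalize_seq(flank3)
  insert_len <- as.integer(insert_len)
  if (!nzchar(flank5) || !nzchar(flank3) || insert_len < 1L)
    stop("flanks must be non-empty and insert_len >= 1", call. = FALSE)
  structure(list(flank5 = flank5, insert_len = insert_len,
                 flank3 = flank3),
            class = "library_construct")
}

#' @export
print.library_construct <- function(x, ...) {
  cat("Bind-n-Seq library construct\n")
  cat("  5'-", x$flank5, strrep("N", x$insert_len), x$flank3, "-3'\n",
      sep = "")
  invisible(x)
}

#' Trim library flanks and filter inserts by length
#'
#' Anchored trimming: the 5' flank is matched against the start of each
#' read and the 3' flank against the end, each within
#' `max_flank_mismatch` substitutions. Reads failing either flank are
#' rejected; reads whose remaining insert is not exactly
#' `construct$insert_len` nucleotides are rejected separately. Nothing
#' errors — every failure is tallied.
#'
#' @param reads Character vector of merged reads, or a FASTQ/FASTA path
#'   (read via [read_sequences()]).
#' @param construct A [library_construct()].
#' @param max_flank_mismatch Substitutions tolerated per flank
#'   (default 1).
#' @return A list of class `trim_result`: `inserts` (character vector),
#'   `n_input`, and `rejected` with counts `flank` and `length`.
#' @export
trim_and_filter <- function(reads, construct = library_construct(),
                            max_flank_mismatch = 1L) {
  reads <- read_sequences(reads)
  reads <- toupper(chartr("u", "U", reads))
  n5 <- nchar(construct$flank5); n3 <- nchar(construct$flank3)
  want <- construct$insert_len
  nr <- nchar(reads)

  long_enough <- nr >= n5 + n3
  flank_ok <- logical(length(reads))
  if (any(long_enough)) {
    idx <- which(long_enough)
    pre <- substr(reads[idx], 1L, n5)
    suf <- substr(reads[idx], nr[idx] - n3 + 1L, nr[idx])
    mm5 <- string_mismatches(pre, construct$flank5)
    mm3 <- string_mismatches(suf, construct$flank3)
    flank_ok[idx] <- mm5 <= max_flank_mismatch & mm3 <= max_flank_mismatch
  }
  inserts <- substr(reads[flank_ok], n5 + 1L, nr[flank_ok] - n3)
  len_ok <- nchar(inserts) == want
  structure(list(inserts = unname(inserts[len_ok]),
                 n_input = length(reads),
                 rejected = c(flank = sum(!flank_ok),
                              length = sum(!len_ok))),
            class = "trim_result")
}

# vectorised per-element mismatch count of fixed-width strings against
# one pattern of the same width; byte comparison keeps this fast on
# multi-million-read pools
string_mismatches <- function(x, pattern) {
  k <- nchar(pattern)
  if (!length(x)) return(integer(0))
  stopifnot(all(nchar(x) == k))
  raw <- charToRaw(paste(x, collapse = ""))
  pr <- rep.int(charToRaw(pattern), length(x))
  as.integer(colSums(matrix(raw != pr, nrow = k)))
}

#' @export
print.trim_result <- function(x, ...) {
  cat("trimmed Bind-n-Seq reads: ", length(x$inserts), "/", x$n_input,
      " inserts retained\n", sep = "")
  cat("  rejected: ", x$rejected[["flank"]], " flank, ",
      x$rejected[["length"]], " length\n", sep = "")
  invisible(x)
}

#' Per-position base counts, frequencies and information content
#'
#' Tabulates `A`/`C`/`G`/`T` at each insert position, normalises to
#' frequencies, and computes the per-position information content
#' `2 + sum_b f_b log2 f_b` in bits (0 for a uniform position, 2 for a
#' fixed base) — the heights used in a sequence logo.
#'
#' @param inserts Character vector of equal-length inserts (a
#'   `trim_result` is accepted).
#' @return An object of class `pfm`: list with `counts` and `freq`
#'   (4 x L matrices, rows `A,C,G,T`), `bits` (length-L vector) and `n`.
#' @examples
#' m <- position_base_matrix(c("AC", "AG", "AT", "AA"))
#' m$freq["A", ]   # 1.00 0.25
#' @export
position_base_matrix <- function(inserts) {
  if (inherits(inserts, "trim_result")) inserts <- inserts$inserts
  if (!length(inserts)) stop("no inserts", call. = FALSE)
  inserts <- toupper(inserts)
  L <- unique(nchar(inserts))
  if (length(L) != 1L)
    stop("inserts have mixed lengths: ", paste(L, collapse = ", "),
         call. = FALSE)
  bases <- c("A", "C", "G", "T")
  m <- matrix(unlist(strsplit(inserts, "")), nrow = L)
  counts <- vapply(seq_len(L), function(p)
    tabulate(factor(m[p, ], levels = bases), nbins = 4L), integer(4))
  dimnames(counts) <- list(bases, seq_len(L))
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(counts = counts, freq = freq,
                 bits = logo_information(freq), n = length(inserts)),
            class = "pfm")
}

#' Sequence-logo information content per position
#'
#' @param matrix A `pfm`, or a frequency matrix with one column per
#'   position whose columns sum to 1.
#' @return Numeric vector of bits per position, each in `[0, 2]`.
#' @examples
#' logo_information(matrix(c(0.25, 0.25, 0.25, 0.25), 4))  # 0
#' logo_information(matrix(c(1, 0, 0, 0), 4))              # 2
#' @export
logo_information <- function(matrix) {
  f <- if (inherits(matrix, "pfm")) matrix$freq else matrix
  if (any(abs(colSums(f) - 1) > 1e-9))
    stop("frequency columns must sum to 1", call. = FALSE)
  plogp <- ifelse(f > 0, f * log2(f), 0)
  unname(2 + colSums(plogp))
}

#' @export
print.pfm <- function(x, digits = 3, ...) {
  cat("position frequency matrix from", x$n, "inserts\n")
  print(round(x$freq, digits))
  cat("information (bits):", paste(round(x$bits, 2), collapse = " "), "\n")
  invisible(x)
}

#' One-sided exact enrichment test for a 2x2 count table
#'
#' Hypergeometric tail probability that the selected library contains at
#' least `count_sel` occurrences, given `count_sel + count_bg` total
#' occurrences distributed over `total_sel` selected and `total_bg`
#' background slots — the one-sided Fisher exact test in the enrichment
#' direction.
#'
#' @param count_sel,total_sel Occurrences and total in the selected pool.
#' @param count_bg,total_bg Occurrences and total in the background pool.
#' @return p-value in `[0, 1]` (vectorised over the four arguments).
#' @examples
#' exact_enrichment_test(5, 5, 0, 5)  # 1/choose(10, 5)
#' @export
exact_enrichment_test <- function(count_sel, total_sel, count_bg,
                                  total_bg) {
  if (any(count_sel < 0 | count_bg < 0 | total_sel < 1 | total_bg < 1))
    stop("counts must be non-negative and totals >= 1", call. = FALSE)
  if (any(count_sel > total_sel | count_bg > total_bg))
    stop("counts cannot exceed totals", call. = FALSE)
  # P(X >= count_sel), X ~ Hypergeom(white = count_sel + count_bg,
  #                                  black = rest, drawn = total_sel)
  phyper(count_sel - 1, count_sel + count_bg,
         total_sel + total_bg - count_sel - count_bg,
         total_sel, lower.tail = FALSE)
}

#' Discriminative k-mer enrichment between selected and background pools
#'
#' Every k-mer occurring in the selected inserts is tested for
#' over-representation relative to the background with the one-sided
#' exact test; counts are sliding-window occurrence counts and totals
#' the number of windows in each pool. E-values apply a Bonferroni-style
#' correction over the number of distinct k-mers tested. This is a
#' deliberate simplification of regular-expression motif elicitation
#' (DREME): exact words only, no degenerate positions.
#'
#' @param selected,background Character vectors of inserts (or
#'   `trim_result` objects).
#' @param k Word length (default 10).
#' @return A data frame of class `enrichment_result` sorted by
#'   (p ascending, count_selected descending, k-mer): columns `kmer`,
#'   `count_selected`, `total_selected`, `count_background`,
#'   `total_background`, `p_value`, `e_value`.
#' @export
kmer_enrichment <- function(selected, background, k = 10L) {
  if (inherits(selected, "trim_result")) selected <- selected$inserts
  if (inherits(background, "trim_result")) background <- background$inserts
  if (!length(selected) || !length(background))
    stop("both pools must be non-empty", call. = FALSE)
  k <- as.integer(k)
  if (any(nchar(c(selected, background)) < k))
    stop("k = ", k, " exceeds the length of some inserts", call. = FALSE)

  sel_k <- count_kmers(toupper(selected), k)
  bg_k <- count_kmers(toupper(background), k)
  total_sel <- sum(sel_k); total_bg <- sum(bg_k)

  kmers <- names(sel_k)
  cs <- as.integer(sel_k)
  cb <- as.integer(bg_k[kmers]); cb[is.na(cb)] <- 0L
  p <- exact_enrichment_test(cs, total_sel, cb, total_bg)
  res <- data.frame(kmer = kmers, count_selected = cs,
                    total_selected = total_sel, count_background = cb,
                    total_background = total_bg, p_value = p,
                    e_value = pmin(p * length(kmers), Inf),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, -res$count_selected, res$kmer), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

# occurrence counts over all sliding windows of width k
count_kmers <- function(x, k) {
  L <- nchar(x)
  words <- unlist(lapply(seq_len(max(L) - k + 1L), function(o) {
    keep <- L >= o + k - 1L
    substr(x[keep], o, o + k - 1L)
  }))
  table(words)
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat("k-mer enrichment: ", nrow(x), " k-mers tested (",
      x$total_selected[1], " selected vs ", x$total_background[1],
      " background windows)\n", sep = "")
  print.data.frame(head(x, n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Read sequences from a character vector, FASTA or FASTQ file
#'
#' @param x Character vector of sequences, or a single path to a FASTA
#'   or FASTQ file (format detected from the first character).
#' @return Character vector of uppercase sequences.
#' @export
read_sequences <- function(x) {
  if (inherits(x, "XStringSet")) return(toupper(as.character(x)))
  if (length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTUNacgtun]+$", x)) {
    first <- substr(readLines(x, n = 1L), 1L, 1L)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    ss <- Biostrings::readBStringSet(x, format = fmt)
    return(toupper(as.character(ss)))
  }
  # in-memory FASTQ record lines, as produced by emit_reads()
  if (length(x) >= 4L && length(x) %% 4L == 0L &&
      startsWith(x[1], "@") && x[3] == "+")
    return(toupper(x[seq(2L, length(x), by = 4L)]))
  toupper(as.character(x))
}
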