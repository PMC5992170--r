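#' Hamming distance between equal-length nucleotide strings
#'
#' Position-wise mismatch count. The wildcard `N` in either string never
#' counts as a mismatch, so a design's specificity string with wildcard
#' repeats scores only its determinate positions. `U` is treated as `T`.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Integer mismatch count.
#' @examples
#' hamming_distance("GGTTAGGGTTAG", "GGTTAGCGTTAG")  # 1
#' @export
hamming_distance <- function(a, b) {
  a <- normalize_seq(a); b <- normalize_seq(b)
  if (nchar(a) != nchar(b))
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b),
         ")", call. = FALSE)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv & av != "N" & bv != "N")
}

normalize_seq <- function(x) {
  x <- toupper(as.character(x))
  if (length(x) != 1L) stop("expected a single sequence", call. = FALSE)
  chartr("U", "T", x)
}

#' Scan a sequence for binding sites of a cPPR design
#'
#' Slides the design's specificity string (its target, with `N` for
#' non-canonical repeats) over every window of the subject sequence and
#' reports windows within the mismatch budget. ssDNA has no strand, so
#' only the given orientation is scanned unless `revcomp = TRUE` is set
#' for double-stranded inputs.
#'
#' @param design A `cppr_design`, or a plain specificity string.
#' @param sequence Subject nucleotide sequence (string, or FASTA path via
#'   [read_target()]).
#' @param max_mismatch Maximum mismatches per reported hit (default 0).
#' @param revcomp Also scan the reverse complement (reported with
#'   `strand = "-"`, coordinates on the forward sequence). Default off.
#' @return A data frame of hits sorted by (mismatches, offset): columns
#'   `offset` (0-based start, half-open window `[offset, offset+L)`),
#'   `end`, `mismatches`, `window`, `strand`. Zero rows (with a warning)
#'   when the sequence is shorter than the design.
#' @examples
#' telo1 <- build_design("TTAGGGTTAG")
#' scan_sequence(telo1, "GGTTAGGGTTAG")  # one hit at offset 2
#' @export
scan_sequence <- function(design, sequence, max_mismatch = 0L,
                          revcomp = FALSE) {
  spec <- if (inherits(design, "cppr_design")) design$target else
    normalize_seq(design)
  sequence <- normalize_seq(sequence)
  L <- nchar(spec)
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0", call. = FALSE)
  scan_one <- function(subj, strand) {
    n <- nchar(subj)
    if (n < L) return(NULL)
    sv <- strsplit(subj, "")[[1]]
    pv <- strsplit(spec, "")[[1]]
    offs <- 0:(n - L)
    mm <- vapply(offs, function(o) {
      w <- sv[(o + 1L):(o + L)]
      sum(w != pv & w != "N" & pv != "N")
    }, integer(1))
    keep <- mm <= max_mismatch
    if (!any(keep)) return(NULL)
    data.frame(offset = offs[keep], end = offs[keep] + L,
               mismatches = mm[keep],
               window = substring(subj, offs[keep] + 1L, offs[keep] + L),
               strand = strand, stringsAsFactors = FALSE)
  }
  if (nchar(sequence) < L) {
    warning("sequence (", nchar(sequence),
            " nt) is shorter than the design (", L, " nt); no windows")
    return(data.frame(offset = integer(), end = integer(),
                      mismatches = integer(), window = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  hits <- scan_one(sequence, "+")
  if (revcomp) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    h2 <- scan_one(rc, "-")
    if (!is.null(h2)) {
      # report on forward coordinates
      h2$offset <- nchar(sequence) - h2$end
      h2$end <- h2$offset + L
      hits <- rbind(hits, h2)
    }
  }
  if (is.null(hits))
    return(data.frame(offset = integer(), end = integer(),
                      mismatches = integer(), window = character(),
                      strand = character(), stringsAsFactors = FALSE))
  hits <- hits[order(hits$mismatches, hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Annotate the telomeric portion of an extension-assay primer
#'
#' Telomerase-assay primers are built as a non-telomeric 5' spacer
#' followed by a 3' stretch of telomeric repeat sequence. This finds the
#' longest 3' suffix of the primer that is a substring of the infinitely
#' repeated unit (default `TTAGGG`, the mammalian telomere repeat) and
#' reports the split plus the phase of the telomeric segment within the
#' repeat unit.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param unit Telomere repeat unit (default `TTAGGG`).
#' @param min_len Minimum telomeric segment length to report; suffixes
#'   shorter than this count as spacer, since matches below one repeat
#'   unit are indistinguishable from chance (any single trailing `T`,
#'   `A` or `G` matches the unit somewhere). Defaults to the unit
#'   length; set to 1 for the literal longest-suffix rule.
#' @return A list of class `telomere_annotation`: `spacer_len`,
#'   `telo_len`, `phase_offset` (0-based position within `unit` where
#'   the telomeric segment starts; `NA` when `telo_len` is 0), `spacer`
#'   and `telo` segments.
#' @examples
#' annotate_telomeric_primer("CTAGACCTGTCATCATTAGGGTTAGGGTTAGGG")
#' # spacer_len 15, telo_len 18
#' @export
annotate_telomeric_primer <- function(primer, unit = "TTAGGG",
                                      min_len = nchar(unit)) {
  primer <- normalize_seq(primer)
  unit <- normalize_seq(unit)
  if (!nzchar(primer) || !nzchar(unit))
    stop("primer and unit must be non-empty", call. = FALSE)
  n <- nchar(primer)
  # enough unit copies that any substring up to the primer length fits
  tandem <- strrep(unit, ceiling(n / nchar(unit)) + 2L)
  telo_len <- 0L
  for (len in n:1) {
    suf <- substr(primer, n - len + 1L, n)
    if (grepl(suf, tandem, fixed = TRUE)) { telo_len <- len; break }
  }
  if (telo_len < min_len) telo_len <- 0L
  phase <- NA_integer_
  if (telo_len > 0L) {
    suf <- substr(primer, n - telo_len + 1L, n)
    rot <- vapply(0:(nchar(unit) - 1L), function(o) {
      substr(tandem, o + 1L, o + telo_len) == suf
    }, logical(1))
    phase <- which(rot)[1] - 1L
  }
  structure(list(spacer_len = n - telo_len, telo_len = telo_len,
                 phase_offset = phase,
                 spacer = substr(primer, 1L, n - telo_len),
                 telo = substr(primer, n - telo_len + 1L, n)),
            class = "telomere_annotation")
}

#' @export
print.telomere_annotation <- function(x, ...) {
  cat("telomeric primer annotation\n")
  cat("  5' spacer: ", x$spacer_len, " nt",
      if (x$spacer_len) paste0(" (", x$spacer, ")"), "\n", sep = "")
  cat("  3' telomeric segment: ", x$telo_len, " nt",
      if (x$telo_len) paste0(" (", x$telo, "), phase offset ",
                             x$phase_offset), "\n", sep = "")
  invisible(x)
}

#' Flag sequences able to form a G-quadruplex
#'
#' Uses the standard G4 consensus: four runs of three or more guanines
#' separated by loops of 1–7 nucleotides. Telomeric G-strand sequences
#' typically satisfy it; this matters when choosing probes because G4
#' folding can compete with protein binding.
#'
#' @param sequence Nucleotide string.
#' @param min_run Minimum G-run length (default 3).
#' @param loop_range Loop length bounds (default `c(1, 7)`).
#' @return Logical.
#' @examples
#' has_g4_motif("GGGTTAGGGTTAGGGTTAGGG")  # TRUE
#' has_g4_motif("GGGTTAGGG")              # FALSE (only two runs)
#' @export
has_g4_motif <- function(sequence, min_run = 3L, loop_range = c(1L, 7L)) {
  sequence <- normalize_seq(sequence)
  run <- paste0("G{", min_run, ",}")
  loop <- paste0("[ACGTN]{", loop_range[1], ",", loop_range[2], "}")
  pat <- paste0(run, loop, run, loop, run, loop, run)
  grepl(pat, sequence)
}
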