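#' The 35-amino-acid consensus repeat template
#'
#' Each cPPR repeat is a copy of a single 35-aa consensus sequence with
#' two variable slots — local positions 5 and 35 — substituted per target
#' base. The remaining positions are structural: a valine at position 2
#' stacks the bound base, a lysine at position 13 binds the phosphate
#' backbone, and the Arg16/Glu18/Glu19 and Glu25/Glu26/Lys28 sets form
#' the inter-repeat hydrogen-bond networks of the solenoid.
#'
#' Templates are loaded from a small key=value config file holding the
#' 35-character sequence and the variable slot positions, and are
#' validated against the fixed-position constraints on load.
#'
#' @param file Path to a template config file with lines
#'   `sequence=<35 aa>` and `variable_positions=5,35`. The default is the
#'   consensus template shipped with the package.
#' @return An object of class `repeat_template`: a list with elements
#'   `sequence` (35-char string) and `variable_positions` (integer
#'   vector).
#' @examples
#' tpl <- repeat_template()
#' tpl$sequence
#' @export
repeat_template <- function(file = system.file("extdata",
                                               "consensus_repeat.txt",
                                               package = "pprkit")) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  conf <- setNames(vals, keys)
  if (!all(c("sequence", "variable_positions") %in% keys))
    stop("template config needs 'sequence' and 'variable_positions'",
         call. = FALSE)
  tpl <- structure(
    list(sequence = toupper(conf[["sequence"]]),
         variable_positions =
           as.integer(strsplit(conf[["variable_positions"]], ",")[[1]])),
    class = "repeat_template")
  validate_template(tpl)
  tpl
}

# Fixed-position constraints a valid consensus repeat must satisfy.
TEMPLATE_FIXED <- c(`2` = "V", `13` = "K", `16` = "R", `18` = "E",
                    `19` = "E", `25` = "E", `26` = "E", `28` = "K")

REPEAT_LEN <- 35L

validate_template <- function(tpl) {
  seq <- tpl$sequence
  if (nchar(seq) != REPEAT_LEN)
    stop("repeat template must be exactly ", REPEAT_LEN,
         " amino acids, got ", nchar(seq), call. = FALSE)
  aa <- strsplit(seq, "")[[1]]
  if (!all(aa %in% AA1))
    stop("repeat template contains non-amino-acid characters", call. = FALSE)
  if (!identical(sort(tpl$variable_positions), c(5L, 35L)))
    stop("variable positions must be 5 and 35", call. = FALSE)
  pos <- as.integer(names(TEMPLATE_FIXED))
  bad <- aa[pos] != TEMPLATE_FIXED
  if (any(bad))
    stop("template violates fixed-position constraint(s): ",
         paste0("position ", pos[bad], " must be ", TEMPLATE_FIXED[bad],
                " (found ", aa[pos][bad], ")", collapse = "; "),
         call. = FALSE)
  invisible(tpl)
}

#' @export
print.repeat_template <- function(x, ...) {
  cat("cPPR consensus repeat template (35 aa)\n")
  cat("  sequence:", x$sequence, "\n")
  cat("  variable positions:", paste(x$variable_positions, collapse = ", "),
      "\n")
  invisible(x)
}
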