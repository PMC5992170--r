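#' Generate a uniform random insert library
#'
#' The unselected ("background") pool of a Bind-n-Seq experiment:
#' independent, uniformly random bases at every position.
#'
#' @param n Number of inserts.
#' @param insert_len Insert length (default 10).
#' @param seed Integer seed; the generator is bit-reproducible for a
#'   given seed and parameter set.
#' @return Character vector of `n` inserts.
#' @examples
#' generate_random_library(3, 10, seed = 1)
#' @export
generate_random_library <- function(n, insert_len = 10L, seed = 1L) {
  n <- as.integer(n); insert_len <- as.integer(insert_len)
  if (n < 1L || insert_len < 1L)
    stop("n and insert_len must be >= 1", call. = FALSE)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  draw_inserts(n, insert_len)
}

# matrix of base indices -> insert strings
draw_inserts <- function(n, insert_len) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(bases[sample.int(4L, n * insert_len, replace = TRUE)],
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# save/seed and restore the RNG so generators do not disturb the
# caller's random state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Select inserts by similarity to a design target
#'
#' Models the protein-bead pull-down as independent Bernoulli retention:
#' an insert at Hamming distance `m` from the design target survives
#' selection with probability `epsilon^m` (`epsilon^0 = 1`, so perfect
#' targets are always kept). `epsilon` in (0,1] is the per-mismatch
#' retention factor; smaller values mean stricter selection. This is the
#' simplest monotone model consistent with binding degrading over a
#' 1 -> 3 -> 5 mismatch series; it makes no attempt to fit measured
#' affinities.
#'
#' @param library Character vector of inserts, all the length of the
#'   target.
#' @param design A `cppr_design` or a target string.
#' @param epsilon Per-mismatch retention factor in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of retained inserts (a subset of `library`,
#'   order preserved).
#' @export
select_library <- function(library, design, epsilon = 0.3, seed = 1L) {
  target <- if (inherits(design, "cppr_design")) design$target else
    normalize_seq(design)
  if (!all(nchar(library) == nchar(target)))
    stop("all inserts must match the target length (", nchar(target),
         ")", call. = FALSE)
  if (epsilon <= 0 || epsilon > 1)
    stop("epsilon must be in (0, 1]", call. = FALSE)
  mm <- string_mismatches(toupper(library), target)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  keep <- runif(length(library)) < epsilon^mm
  library[keep]
}

#' Wrap inserts into flanked FASTQ reads
#'
#' Each insert is embedded between the construct flanks; optional
#' uniform substitution errors are applied over the whole read
#' (sequencing-error model; indels are not modelled). Qualities are a
#' constant placeholder.
#'
#' @param inserts Character vector of inserts.
#' @param construct A [library_construct()].
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param file Optional path; when given, FASTQ is written there.
#' @return Invisibly when `file` is given, otherwise visibly: a
#'   character vector of FASTQ records (4 lines per read, collapsed with
#'   newlines on write).
#' @export
emit_reads <- function(inserts, construct = library_construct(),
                       error_rate = 0, seed = 1L, file = NULL) {
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)
  seqs <- paste0(construct$flank5, toupper(inserts), construct$flank3)
  if (length(inserts) && error_rate > 0) {
    old <- local_rng(seed)
    on.exit(restore_rng(old))
    bases <- c("A", "C", "G", "T")
    chars <- strsplit(seqs, "")
    L <- nchar(seqs[1])
    seqs <- vapply(chars, function(v) {
      hit <- runif(length(v)) < error_rate
      if (any(hit)) {
        # substitute with one of the three other bases
        v[hit] <- vapply(v[hit], function(b)
          sample(setdiff(bases, b), 1L), "")
      }
      paste(v, collapse = "")
    }, "")
  }
  if (!length(inserts)) {
    recs <- character(0)
  } else {
    qual <- strrep("I", nchar(seqs))
    recs <- as.vector(rbind(paste0("@read", seq_along(seqs)), seqs,
                            "+", qual))
  }
  if (!is.null(file)) {
    writeLines(recs, file)
    return(invisible(recs))
  }
  recs
}

#' Simulate a full Bind-n-Seq experiment
#'
#' Generates a background pool of uniform inserts and a selected pool by
#' rejection sampling under the `epsilon^m` retention model, then
#' (optionally) wraps both in flanked FASTQ reads. The selected pool is
#' drawn until `n` inserts survive, so both pools have equal depth.
#'
#' @param design A `cppr_design` or target string the selection favours.
#' @param n Reads per pool (default 20000).
#' @param epsilon Per-mismatch retention factor (default 0.3).
#' @param error_rate Substitution error rate for read emission.
#' @param seed Integer seed.
#' @param construct A [library_construct()]; its `insert_len` must match
#'   the target length.
#' @param out_selected,out_background Optional FASTQ output paths.
#' @return A list with `selected` and `background` insert vectors, plus
#'   `reads_selected`/`reads_background` FASTQ record vectors.
#' @export
simulate_bindnseq <- function(design, n = 20000L, epsilon = 0.3,
                              error_rate = 0, seed = 42L,
                              construct = library_construct(),
                              out_selected = NULL, out_background = NULL) {
  target <- if (inherits(design, "cppr_design")) design$target else
    normalize_seq(design)
  if (construct$insert_len != nchar(target))
    stop("construct insert_len (", construct$insert_len,
         ") must equal the target length (", nchar(target), ")",
         call. = FALSE)
  n <- as.integer(n)
  background <- generate_random_library(n, nchar(target), seed = seed)

  # rejection-sample the selected pool in chunks; expected acceptance is
  # E[eps^m] = ((1 + 3*eps)/4)^L over uniform inserts. Same model as
  # generate_random_library + select_library, but retention is decided
  # on the integer base matrix so only survivors are materialised as
  # strings (the acceptance probability makes the pool ~1/acc times n).
  L <- nchar(target)
  tgt_idx <- match(strsplit(target, "")[[1]], c("A", "C", "G", "T"))
  acc <- ((1 + 3 * epsilon) / 4)^L
  bases <- c("A", "C", "G", "T")
  selected <- character(0)
  chunk_seed <- seed
  while (length(selected) < n) {
    chunk_seed <- chunk_seed + 1L
    todo <- n - length(selected)
    draw <- min(4000000L, max(10000L, ceiling(1.2 * todo / acc)))
    old <- local_rng(chunk_seed)
    m <- matrix(sample.int(4L, draw * L, replace = TRUE), ncol = L)
    mm <- rowSums(m != matrix(tgt_idx, draw, L, byrow = TRUE))
    keep <- which(runif(draw) < epsilon^mm)
    restore_rng(old)
    if (length(keep)) {
      km <- matrix(bases[m[keep, , drop = FALSE]], ncol = L)
      selected <- c(selected,
                    do.call(paste0,
                            as.data.frame(km, stringsAsFactors = FALSE)))
    }
  }
  selected <- selected[seq_len(n)]

  out <- list(selected = selected, background = background)
  out$reads_selected <- emit_reads(selected, construct,
                                   error_rate = error_rate,
                                   seed = seed + 1L, file = out_selected)
  out$reads_background <- emit_reads(background, construct,
                                     error_rate = error_rate,
                                     seed = seed + 2L,
                                     file = out_background)
  invisible(out)
}
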