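# Deterministic global alignment for short miRNA/pre-miRNA sequences.
# Scoring is fixed (match +1, mismatch -1, gap -2, terminal gaps free): for
# ~22 nt matures this is auditable and reproducible, and pre-aligned input is
# accepted everywhere an alignment is consumed, so an external aligner can be
# substituted when exactness against a particular program matters.

#' Pairwise global alignment with free end gaps
#'
#' Needleman-Wunsch with match +1, mismatch -1, gap -2 and cost-free terminal
#' gaps. Tie-breaks are fixed (diagonal, then gap-in-`b`, then gap-in-`a`), so
#' the result is deterministic.
#'
#' @param a,b RNA strings.
#' @return List with gapped strings `a` and `b` (equal length, gap `"-"`) and
#'   the alignment `score`.
#' @examples
#' nw_align("ACGU", "AGU")
#' @export
nw_align <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, nzchar(a),
            is.character(b), length(b) == 1L, nzchar(b))
  .nw_align_cpp(a, b)
}

#' Construct an aligned miRNA family
#'
#' A gapped alignment of one miRNA (one arm) across species: equal-length
#' rows named by species code, one of which is the reference (human by
#' default). This is the substrate of [trim_core()], [divergence_profile()]
#' and [diversity_stats()].
#'
#' @param rows named character vector of gapped sequences (gap `"-"`), equal
#'   lengths, at least two rows.
#' @param reference name of the reference row; default `"hsa"`.
#' @param name,arm optional family name and arm label (`"5p"`/`"3p"`).
#' @return Object of class `aligned_family`.
#' @export
aligned_family <- function(rows, reference = "hsa", name = NULL, arm = NULL) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (length(rows) < 2L) stop("an aligned family needs >= 2 rows", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L) {
    stop("aligned rows must have equal lengths", call. = FALSE)
  }
  if (!reference %in% names(rows)) {
    stop("reference row '", reference, "' not present", call. = FALSE)
  }
  structure(list(rows = rows, reference = reference, name = name, arm = arm),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("Aligned family%s%s: %d rows x %d columns (reference %s)\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              if (is.null(x$arm)) "" else paste0("-", x$arm),
              length(x$rows), nchar(x$rows[[1L]]), x$reference))
  invisible(x)
}

#' Star alignment of a family around its reference
#'
#' Aligns every sequence pairwise to the reference with [nw_align()] and
#' merges the pairwise alignments on reference coordinates: insertions
#' relative to the reference open shared gap columns (sized by the longest
#' insertion at that point; shorter insertions are right-aligned against the
#' following reference column).
#'
#' @param seqs named character vector of ungapped RNA sequences.
#' @param reference name of the reference sequence; default `"hsa"`.
#' @inheritParams aligned_family
#' @return `aligned_family`.
#' @export
star_align <- function(seqs, reference = "hsa", name = NULL, arm = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (!reference %in% names(seqs)) {
    stop("reference sequence '", reference, "' not present", call. = FALSE)
  }
  ref <- seqs[[reference]]
  others <- setdiff(names(seqs), reference)
  R <- nchar(ref)
  pas <- lapply(seqs[others], function(s) nw_align(ref, s))
  # ins[t, r]: gap columns in the reference row immediately before reference
  # position r in pairwise alignment t (slot R+1 = after the last position)
  ins <- matrix(0L, nrow = length(others), ncol = R + 1L)
  for (t in seq_along(pas)) {
    ar <- strsplit(pas[[t]]$a, "", fixed = TRUE)[[1L]]
    r <- 1L
    run <- 0L
    for (ch in ar) {
      if (ch == "-") run <- run + 1L
      else { ins[t, r] <- run; run <- 0L; r <- r + 1L }
    }
    ins[t, R + 1L] <- run
  }
  master <- if (nrow(ins)) apply(ins, 2L, max) else integer(R + 1L)
  place_row <- function(arow, brow) {
    # walk the pairwise alignment, emitting per reference slot
    out <- character(0L)
    i <- 1L
    for (r in seq_len(R + 1L)) {
      run <- character(0L)
      while (i <= length(arow) && arow[i] == "-") {
        run <- c(run, brow[i])
        i <- i + 1L
      }
      out <- c(out, rep("-", master[r] - length(run)), run)
      if (r <= R) {
        out <- c(out, brow[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }
  rows <- setNames(character(length(seqs)), names(seqs))
  refrow <- character(0L)
  refch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  for (r in seq_len(R)) refrow <- c(refrow, rep("-", master[r]), refch[r])
  rows[reference] <- paste(c(refrow, rep("-", master[R + 1L])), collapse = "")
  for (t in seq_along(pas)) {
    rows[others[t]] <- place_row(strsplit(pas[[t]]$a, "", fixed = TRUE)[[1L]],
                                 strsplit(pas[[t]]$b, "", fixed = TRUE)[[1L]])
  }
  if (length(seqs) >= 2L) {
    aligned_family(rows, reference = reference, name = name, arm = arm)
  } else {
    structure(list(rows = rows, reference = reference, name = name, arm = arm),
              class = "aligned_family")
  }
}
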