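# Length, nucleotide, homopolymer-run and positional composition of mature
# miRNA groups, and the between-group tests used to compare 5p vs 3p arms.

group_seqs <- function(group, what = "group") {
  seqs <- if (is.data.frame(group)) group$sequence else as.character(group)
  if (!length(seqs)) stop("empty ", what, call. = FALSE)
  check_rna(seqs, what)
  seqs
}

#' Summarise sequence lengths of a miRNA group
#'
#' @param group data frame of mature records, character vector of sequences,
#'   or numeric vector of lengths.
#' @return Object of class `length_summary`: `n`, `mean`, `sem`
#'   (`sd/sqrt(n)`; 0 when `n == 1`), `values`.
#' @examples
#' length_summary(c(20, 24)) # mean 22, sem 2
#' @export
length_summary <- function(group) {
  lens <- if (is.numeric(group)) as.numeric(group)
          else nchar(group_seqs(group))
  if (!length(lens)) stop("empty group", call. = FALSE)
  s <- if (length(lens) > 1L) sd(lens) else 0
  structure(list(n = length(lens), mean = mean(lens),
                 sem = s / sqrt(length(lens)), values = lens),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("Length summary: n = %d, mean = %.2f +/- %.2f (SEM)\n",
              x$n, x$mean, x$sem))
  invisible(x)
}

#' Compare length distributions of two miRNA groups
#'
#' Two-tailed t test: Student's (pooled-variance) t for independent groups
#' (e.g. all 5p-miRNAs vs all 3p-miRNAs), or a paired t test for matched
#' miR-#-5p/miR-#-3p pairs (operating on per-pair differences).
#'
#' @param a,b groups as in [length_summary()]; in paired mode they must align
#'   element-wise and have equal length.
#' @param paired logical.
#' @return `htest` object from [stats::t.test()].
#' @export
length_compare <- function(a, b, paired = FALSE) {
  la <- if (is.numeric(a)) as.numeric(a) else nchar(group_seqs(a, "group a"))
  lb <- if (is.numeric(b)) as.numeric(b) else nchar(group_seqs(b, "group b"))
  if (length(la) < 2L || length(lb) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (paired && length(la) != length(lb)) {
    stop("paired mode requires equal-length paired lists", call. = FALSE)
  }
  t.test(la, lb, paired = paired, var.equal = !paired)
}

composition_table <- function(labels, counts) {
  total <- sum(counts)
  structure(data.frame(label = labels, count = as.numeric(counts),
                       percent = if (total > 0) 100 * counts / total
                                 else rep(NA_real_, length(counts)),
                       stringsAsFactors = FALSE),
            class = c("composition_table", "data.frame"))
}

#' Overall nucleotide composition of a miRNA group
#'
#' Counts of A/U/C/G pooled over all sequences, with percents of the total.
#'
#' @param group data frame of mature records or character vector of sequences.
#' @return `composition_table` data frame: `label`, `count`, `percent`.
#' @export
nucleotide_composition <- function(group) {
  seqs <- group_seqs(group)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  counts <- vapply(c("A", "U", "C", "G"), function(b) sum(chars == b), 0)
  composition_table(c("A", "U", "C", "G"), counts)
}

#' Homopolymer-run composition (AA/UU/CC/GG and longer)
#'
#' Counts overlapping occurrences of the four homopolymer k-mers (`AA..`,
#' `UU..`, `CC..`, `GG..`) pooled over the group: a run of m identical
#' nucleotides contributes m - k + 1 k-mers. Percents are normalised over
#' the four homopolymer labels only, so each column totals 100.
#'
#' @param group as in [nucleotide_composition()].
#' @param k homopolymer length, one of 2, 3, 4.
#' @return `composition_table` with labels like `"GG"` (k = 2).
#' @examples
#' repeat_run_composition("GGG", k = 2) # two overlapping GG
#' @export
repeat_run_composition <- function(group, k) {
  if (!(length(k) == 1L && k %in% 2:4)) {
    stop("k must be one of 2, 3, 4", call. = FALSE)
  }
  seqs <- group_seqs(group)
  bases <- c("A", "U", "C", "G")
  counts <- setNames(numeric(4L), bases)
  for (s in seqs) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    keep <- r$lengths >= k
    if (any(keep)) {
      add <- tapply(r$lengths[keep] - k + 1L, r$values[keep], sum)
      counts[names(add)] <- counts[names(add)] + add
    }
  }
  composition_table(vapply(bases, function(b) strrep(b, k), character(1)),
                    unname(counts))
}

#' Per-position nucleotide composition
#'
#' Nucleotide percents at each position counted 5' to 3' from 1 (left
#' anchored); each position is computed over the sequences long enough to
#' cover it, and each covered row sums to 100.
#'
#' @param group as in [nucleotide_composition()].
#' @return Object of class `positional_composition`: list with `counts`
#'   (positions x ACUG matrix), `percent` (same shape), `coverage` (sequences
#'   covering each position).
#' @export
positional_composition <- function(group) {
  seqs <- group_seqs(group)
  lmax <- max(nchar(seqs))
  bases <- c("A", "U", "C", "G")
  counts <- matrix(0, nrow = lmax, ncol = 4L,
                   dimnames = list(seq_len(lmax), bases))
  for (s in seqs) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    idx <- cbind(seq_along(ch), match(ch, bases))
    counts[idx] <- counts[idx] + 1
  }
  coverage <- rowSums(counts)
  percent <- 100 * counts / ifelse(coverage > 0, coverage, NA_real_)
  structure(list(counts = counts, percent = percent, coverage = coverage),
            class = "positional_composition")
}

#' @export
print.positional_composition <- function(x, ...) {
  cat("Positional nucleotide composition,", nrow(x$counts), "positions\n")
  print(round(utils::head(x$percent, 10L), 2))
  invisible(x)
}

comp_counts <- function(x) {
  if (inherits(x, "positional_composition")) {
    cts <- as.vector(t(x$counts))
    names(cts) <- paste0(rep(rownames(x$counts), each = 4L),
                         colnames(x$counts)[rep(1:4, nrow(x$counts))])
    return(cts)
  }
  if (inherits(x, "composition_table") ||
      (is.data.frame(x) && all(c("label", "count") %in% names(x)))) {
    return(setNames(x$count, x$label))
  }
  if (is.numeric(x)) return(x)
  stop("cannot extract counts from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Pearson chi-square comparison of two composition tables
#'
#' Builds the groups x labels contingency table from the raw counts and runs
#' an (uncorrected) Pearson chi-square test. For positional input the
#' position-by-nucleotide counts are stacked into one pooled contingency
#' (restricted to positions present in both groups). Cells empty in both
#' groups are dropped (they carry no information); a zero expected count
#' elsewhere is an error suggesting category merging. Symmetric in its two
#' arguments.
#'
#' @param table_a,table_b `composition_table`s, `positional_composition`s, or
#'   named count vectors with matching labels.
#' @return `htest` with `statistic` (X-squared), `parameter` (df), `p.value`.
#' @export
chi_square_compare <- function(table_a, table_b) {
  pos <- inherits(table_a, "positional_composition")
  if (pos != inherits(table_b, "positional_composition")) {
    stop("cannot mix positional and overall composition tables", call. = FALSE)
  }
  if (pos) {
    pmin_ <- min(nrow(table_a$counts), nrow(table_b$counts))
    table_a$counts <- table_a$counts[seq_len(pmin_), , drop = FALSE]
    table_b$counts <- table_b$counts[seq_len(pmin_), , drop = FALSE]
  }
  ca <- comp_counts(table_a)
  cb <- comp_counts(table_b)
  if (length(ca) != length(cb) ||
      (!is.null(names(ca)) && !is.null(names(cb)) &&
       !identical(names(ca), names(cb)))) {
    stop("composition tables have mismatching labels", call. = FALSE)
  }
  keep <- ca + cb > 0
  mat <- rbind(a = ca[keep], b = cb[keep])
  expected <- outer(rowSums(mat), colSums(mat)) / sum(mat)
  if (any(expected <= 0)) {
    stop("zero expected count in contingency table; ",
         "merge sparse categories before testing", call. = FALSE)
  }
  suppressWarnings(chisq.test(mat, correct = FALSE))
}
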