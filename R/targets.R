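# Seed-based target analysis: seed extraction (mature positions 2-8), 5'
# seed-shift detection, exact seed-match scanning over UTR sequences, and
# overlap statistics between target sets. The match rule is deliberately a
# plain exact 7-mer reverse-complement scan (no 7mer-m8/8mer/A1 site-type
# distinction, no context or conservation scores): do not read TargetScan
# equivalence into these results.

#' Extract the seed sequence of a mature miRNA or isomiR
#'
#' The seed is nucleotides 2-8 (1-based) of the 5' end, the primary
#' determinant of target recognition.
#'
#' @param x RNA string (or record) of length at least 8 nt.
#' @param id optional source id recorded with the seed.
#' @return Object of class `seed_sequence`: `source_id`, `seed` (7-mer).
#' @examples
#' extract_seed("UGAGGUAGUAGGUUGUAUAGUU")$seed # "GAGGUAG"
#' @export
extract_seed <- function(x, id = NULL) {
  s <- record_seq(x)
  if (nchar(s) < 8L) {
    stop("sequence shorter than 8 nt has no seed", call. = FALSE)
  }
  structure(list(source_id = id %||% record_id(x, NA_character_),
                 seed = substr(s, 2L, 8L)),
            class = "seed_sequence")
}

#' Detect seed shifting of a 5' isomiR
#'
#' A 5' end shift (`offset5 != 0`) relocates the 2-8 nt window and usually -
#' but not always (homopolymeric 5' ends) - changes the seed; both facts are
#' reported.
#'
#' @param canonical canonical mature record or RNA string.
#' @param isomir isomiR row from [extract_isomirs()] (needs `offset5` and
#'   `sequence`), or a list with those fields.
#' @return List: `shifted` (logical, `offset5 != 0`), `magnitude`
#'   (`abs(offset5)`), `seed_changed` (logical), `seed_canonical`,
#'   `seed_isomir`.
#' @export
detect_seed_shift <- function(canonical, isomir) {
  off5 <- if (is.data.frame(isomir)) isomir$offset5[1L] else isomir$offset5
  iseq <- record_seq(if (is.data.frame(isomir)) isomir[1L, ] else isomir)
  cseed <- extract_seed(canonical)$seed
  iseed <- extract_seed(iseq)$seed
  list(shifted = off5 != 0L, magnitude = abs(off5),
       seed_changed = !identical(cseed, iseed),
       seed_canonical = cseed, seed_isomir = iseed)
}

utr_table <- function(utrs) {
  if (is.data.frame(utrs)) {
    stopifnot(all(c("id", "sequence") %in% names(utrs)))
    tb <- utrs[, c("id", "sequence")]
  } else if (inherits(utrs, "XStringSet")) {
    tb <- data.frame(id = names(utrs), sequence = as.character(utrs),
                     stringsAsFactors = FALSE)
  } else if (is.character(utrs) && !is.null(names(utrs))) {
    tb <- data.frame(id = names(utrs), sequence = unname(utrs),
                     stringsAsFactors = FALSE)
  } else {
    stop("UTRs must be a data frame (id, sequence), a named character ",
         "vector, or an XStringSet", call. = FALSE)
  }
  tb$sequence <- normalize_rna(tb$sequence)
  tb[!duplicated(tb$id), , drop = FALSE]   # dedup on id, keep first
}

#' Scan UTRs for exact seed matches
#'
#' A UTR is a target when it contains at least one exact occurrence of the
#' reverse complement of the 7-mer seed; every occurrence interval is
#' recorded. DNA input is normalised to RNA before matching; duplicate UTR
#' ids are deduplicated (first kept).
#'
#' @param seed `seed_sequence` from [extract_seed()] or a 7-mer RNA string.
#' @param utrs UTR records: data frame `id`, `sequence`, a named character
#'   vector, or a `Biostrings::XStringSet`.
#' @return Object of class `target_set`: `source_id`, `utr_ids` (targets),
#'   `positions` (named list of 1-based match start vectors; each match spans
#'   7 nt), `n_scanned`.
#' @export
scan_targets <- function(seed, utrs) {
  src <- NA_character_
  if (inherits(seed, "seed_sequence")) {
    src <- seed$source_id
    seed <- seed$seed
  }
  seed <- normalize_rna(seed)
  if (nchar(seed) != 7L) stop("seed must be exactly 7 nt", call. = FALSE)
  tb <- utr_table(utrs)
  if (!nrow(tb)) stop("UTR set is empty", call. = FALSE)
  site <- rna_revcomp(seed)
  hits <- lapply(tb$sequence, function(s) {
    h <- gregexpr(site, s, fixed = TRUE)[[1L]]
    if (h[1L] == -1L) integer(0) else as.integer(h)
  })
  names(hits) <- tb$id
  has <- lengths(hits) > 0L
  structure(list(source_id = src, utr_ids = tb$id[has],
                 positions = hits[has], n_scanned = nrow(tb)),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("Target set%s: %d/%d UTRs, %d sites\n",
              if (is.na(x$source_id)) "" else paste0(" for ", x$source_id),
              length(x$utr_ids), x$n_scanned, sum(lengths(x$positions))))
  invisible(x)
}

#' Overlap statistics between two target sets
#'
#' Set arithmetic on target UTR ids (match positions are ignored): shared
#' count, fraction of each set shared, and the Jaccard index.
#'
#' @param a,b `target_set`s or character vectors of UTR ids.
#' @return List: `shared`, `fraction_a`, `fraction_b`, `jaccard` (fractions
#'   are `NA` for empty sets; Jaccard is `NA` when both sets are empty).
#' @export
overlap_stats <- function(a, b) {
  ids <- function(x) if (inherits(x, "target_set")) x$utr_ids
                     else unique(as.character(x))
  sa <- unique(ids(a))
  sb <- unique(ids(b))
  shared <- length(intersect(sa, sb))
  uni <- length(union(sa, sb))
  list(shared = shared,
       fraction_a = if (length(sa)) shared / length(sa) else NA_real_,
       fraction_b = if (length(sb)) shared / length(sb) else NA_real_,
       jaccard = if (uni) shared / uni else NA_real_)
}
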