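#' Parse a miRBase-dialect FASTA file
#'
#' Reads hairpin (pre-miRNA) or mature miRNA sequences from a FASTA file whose
#' headers follow the miRBase convention `>id accession description...`, e.g.
#' `>hsa-let-7a-5p MIMAT0000062 Homo sapiens let-7a-5p`. Sequences are
#' uppercased and DNA `T` is normalised to RNA `U`. The species code is taken
#' as the first hyphen-delimited token of the id (`hsa`, `mmu`, ...).
#'
#' miRBase matures are expected to be 15-30 nt and hairpins at least 40 nt;
#' these are conventions of the source database, not hard parse errors.
#'
#' @param path path to a FASTA file.
#' @param kind `"hairpin"` or `"mature"`; recorded in the result and used by
#'   downstream helpers.
#' @return A data frame with one row per entry and columns `id`, `accession`,
#'   `species`, `sequence`, `length`, plus attribute `kind`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-let-7a-5p MIMAT0000062", "UGAGGUAGUAGGUUGUAUAGUU"), fa)
#' parse_mirbase_fasta(fa, "mature")
#' @export
parse_mirbase_fasta <- function(path, kind = c("hairpin", "mature")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA in '", path, "': line ", nonblank[1L],
         " is not a header: ", lines[nonblank[1L]], call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    out <- data.frame(id = character(), accession = character(),
                      species = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE)
    attr(out, "kind") <- kind
    return(out)
  }
  toks <- strsplit(trimws(names(set)), "\\s+")
  id <- vapply(toks, `[`, character(1), 1L)
  if (anyDuplicated(id)) {
    stop("duplicate ids in '", path, "': ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  accession <- vapply(toks, function(t) if (length(t) >= 2L) t[2L] else "",
                      character(1))
  seqs <- normalize_rna(as.character(set))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("malformed FASTA in '", path, "': non-nucleotide characters in entry ",
         id[which(bad)[1L]], call. = FALSE)
  }
  out <- data.frame(id = unname(id), accession = unname(accession),
                    species = sub("-.*$", "", id), sequence = unname(seqs),
                    length = nchar(seqs), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  out
}

#' Write miRNA records back to FASTA
#'
#' Inverse of [parse_mirbase_fasta()]: headers are `id accession` (accession
#' omitted when empty).
#'
#' @param records data frame with `id`, `sequence` and optionally `accession`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(records, path) {
  acc <- records$accession %||% rep("", nrow(records))
  hdr <- ifelse(nzchar(acc), paste(records$id, acc), records$id)
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Locate a mature miRNA on its hairpin
#'
#' Finds the first exact occurrence of the mature sequence in the hairpin
#' sequence and returns 1-based inclusive coordinates. If the mature occurs
#' more than once a warning is emitted and the first (5'-most) hit is taken.
#'
#' @param mature mature record (one-row data frame) or RNA string.
#' @param hairpin hairpin record or RNA string.
#' @return Named integer vector `c(start, end)`, with attribute `n_hits`.
#' @examples
#' locate_mature("ACGU", "GGACGUCC") # c(start = 3, end = 6)
#' @export
locate_mature <- function(mature, hairpin) {
  mseq <- record_seq(mature)
  hseq <- record_seq(hairpin)
  hits <- gregexpr(mseq, hseq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    stop("mature sequence ", record_id(mature, mseq),
         " not found on hairpin ", record_id(hairpin, ""), call. = FALSE)
  }
  if (length(hits) > 1L) {
    warning("mature ", record_id(mature, mseq), " occurs ", length(hits),
            " times on hairpin ", record_id(hairpin, ""),
            "; taking the first occurrence", call. = FALSE)
  }
  out <- c(start = as.integer(hits[1L]),
           end = as.integer(hits[1L]) + nchar(mseq) - 1L)
  attr(out, "n_hits") <- length(hits)
  out
}

#' Classify the arm of origin of a mature miRNA
#'
#' Existing annotation wins: an id ending in `-5p`/`-3p` is classified by name
#' (`method = "name_suffix"`). Otherwise the mature is located on the hairpin
#' and classified positionally: with midpoint `m = (start + end) / 2` and
#' hairpin length `L`, the arm is `5p` when `m < L/2`, `3p` when `m > L/2`,
#' and `ambiguous` when `|m - L/2| <= tie_tolerance` (the mature straddles the
#' loop and no call is forced).
#'
#' @param mature mature record or RNA string (needs an id for the name rule).
#' @param hairpin hairpin record or RNA string.
#' @param tie_tolerance half-width (nt) of the midpoint tie zone; default 1.
#' @param location optional precomputed `c(start, end)` overriding the
#'   substring search.
#' @return One-row data frame: `mature_id`, `hairpin_id`, `arm`, `method`,
#'   `start`, `end` (coordinates `NA` if the mature cannot be located and the
#'   name rule applied).
#' @export
assign_arm <- function(mature, hairpin, tie_tolerance = 1, location = NULL) {
  mid <- record_id(mature)
  hid <- record_id(hairpin)
  loc <- location
  if (is.null(loc)) {
    loc <- tryCatch(suppressWarnings(locate_mature(mature, hairpin)),
                    error = function(e) NULL)
  }
  suffix <- if (!is.na(mid) && grepl("-(5p|3p)$", mid)) sub("^.*-", "", mid)
            else NA_character_
  if (!is.na(suffix)) {
    arm <- suffix
    method <- "name_suffix"
  } else {
    if (is.null(loc)) {
      stop("cannot classify ", mid %||% "<unnamed mature>",
           ": no -5p/-3p suffix and mature not located on hairpin ",
           hid, call. = FALSE)
    }
    L <- nchar(record_seq(hairpin))
    m <- (loc[["start"]] + loc[["end"]]) / 2
    arm <- if (abs(m - L / 2) <= tie_tolerance) "ambiguous"
           else if (m < L / 2) "5p" else "3p"
    method <- "positional"
  }
  data.frame(mature_id = mid, hairpin_id = hid, arm = arm, method = method,
             start = if (is.null(loc)) NA_integer_ else loc[["start"]],
             end = if (is.null(loc)) NA_integer_ else loc[["end"]],
             stringsAsFactors = FALSE)
}

# candidate hairpins for a mature: name-stem match (mature id minus -5p/-3p is
# the hairpin id or its prefix before a copy number) filtered to those
# containing the sequence; fallback: any hairpin containing the sequence.
# Order follows the hairpin input; the first listed hairpin wins downstream.
candidate_hairpins <- function(mature_id, mature_seq, hairpins) {
  stem <- sub("-(5p|3p)$", "", mature_id)
  stem <- sub("miR", "mir", stem, fixed = TRUE)
  hid <- sub("miR", "mir", hairpins$id, fixed = TRUE)
  by_name <- hid == stem | startsWith(hid, paste0(stem, "-"))
  contains <- vapply(hairpins$sequence, grepl, logical(1),
                     pattern = mature_seq, fixed = TRUE, USE.NAMES = FALSE)
  cand <- which(by_name & contains)
  if (!length(cand)) cand <- which(contains)
  hairpins$id[cand]
}

#' Annotate arms for a set of matures against a set of hairpins
#'
#' For every mature the candidate hairpins are found (explicit coordinate
#' table if supplied, else name-stem + substring matching, else substring
#' only); only the first listed hairpin is used when a mature maps to several
#' (multicopy pre-miRNAs). Each locatable mature gets one [assign_arm()] row.
#'
#' @param matures,hairpins data frames from [parse_mirbase_fasta()].
#' @param locations optional data frame `mature_id, hairpin_id, start, end`
#'   overriding the substring search (see [read_locations_tsv()]).
#' @param tie_tolerance passed to [assign_arm()].
#' @return List with `annotations` (one row per placed mature) and `unplaced`
#'   (ids of matures matching no hairpin).
#' @export
annotate_arms <- function(matures, hairpins, locations = NULL,
                          tie_tolerance = 1) {
  ann <- vector("list", nrow(matures))
  unplaced <- character()
  for (i in seq_len(nrow(matures))) {
    m <- matures[i, , drop = FALSE]
    loc <- NULL
    if (!is.null(locations) && m$id %in% locations$mature_id) {
      l <- locations[locations$mature_id == m$id, , drop = FALSE][1L, ]
      hid <- l$hairpin_id
      loc <- c(start = as.integer(l$start), end = as.integer(l$end))
    } else {
      cands <- candidate_hairpins(m$id, m$sequence, hairpins)
      if (!length(cands)) {
        unplaced <- c(unplaced, m$id)
        next
      }
      hid <- cands[1L]
    }
    h <- hairpins[hairpins$id == hid, , drop = FALSE]
    if (!nrow(h)) {
      unplaced <- c(unplaced, m$id)
      next
    }
    ann[[i]] <- suppressWarnings(
      assign_arm(m, h, tie_tolerance = tie_tolerance, location = loc))
  }
  ann <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
  if (is.null(ann)) {
    ann <- data.frame(mature_id = character(), hairpin_id = character(),
                      arm = character(), method = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  list(annotations = ann, unplaced = unplaced)
}

#' Pair 5p and 3p matures on their common hairpin
#'
#' A hairpin contributes one pair exactly when it carries one 5p and one 3p
#' mature (ambiguous loop-spanning matures never enter pairs). Matures on
#' multiple hairpins are placed on the first listed hairpin only.
#'
#' @inheritParams annotate_arms
#' @return List with `pairs` (data frame: `hairpin_id`, `mature_5p`,
#'   `mature_3p` and their sequences/coordinates), `unpaired` (annotation rows
#'   not in any pair) and `unplaced` (ids matching no hairpin).
#' @export
pair_arms <- function(matures, hairpins, locations = NULL, tie_tolerance = 1) {
  aa <- annotate_arms(matures, hairpins, locations, tie_tolerance)
  ann <- aa$annotations
  pairs <- list()
  paired_rows <- logical(nrow(ann))
  for (hid in unique(ann$hairpin_id)) {
    idx <- which(ann$hairpin_id == hid)
    sub <- ann[idx, , drop = FALSE]
    i5 <- idx[sub$arm == "5p"]
    i3 <- idx[sub$arm == "3p"]
    if (length(i5) == 1L && length(i3) == 1L) {
      a5 <- ann[i5, ]; a3 <- ann[i3, ]
      pairs[[length(pairs) + 1L]] <- data.frame(
        hairpin_id = hid,
        mature_5p = a5$mature_id, start_5p = a5$start, end_5p = a5$end,
        mature_3p = a3$mature_id, start_3p = a3$start, end_3p = a3$end,
        stringsAsFactors = FALSE)
      paired_rows[c(i5, i3)] <- TRUE
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(hairpin_id = character(), mature_5p = character(),
                           start_5p = integer(), end_5p = integer(),
                           mature_3p = character(), start_3p = integer(),
                           end_3p = integer(), stringsAsFactors = FALSE)
  list(pairs = pairs, unpaired = ann[!paired_rows, , drop = FALSE],
       unplaced = aa$unplaced)
}

#' Read a mature-on-hairpin coordinate table
#'
#' Three/four-column TSV `mature_id, hairpin_id, start-end` (or separate
#' `start`, `end` columns), 1-based inclusive, overriding substring search.
#'
#' @param path TSV path.
#' @return Data frame `mature_id, hairpin_id, start, end`.
#' @export
read_locations_tsv <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mature_id", "hairpin_id") %in% names(tb))) {
    stop("locations TSV needs mature_id and hairpin_id columns", call. = FALSE)
  }
  if (!all(c("start", "end") %in% names(tb))) {
    span <- tb[[3L]]
    parts <- strsplit(as.character(span), "-", fixed = TRUE)
    tb$start <- as.integer(vapply(parts, `[`, character(1), 1L))
    tb$end <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  tb[, c("mature_id", "hairpin_id", "start", "end")]
}
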