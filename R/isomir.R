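# IsomiR extraction and quantification from collapsed small-RNA read sets:
# each miRNA locus yields multiple 5'/3' end variants plus non-template 3'
# additions; expression is summarised as RPM and as the within-locus relative
# expression percentage, then compared across samples.

#' Construct a collapsed read set
#'
#' @param sample_id sample identifier.
#' @param condition `"disease"` or `"control"`.
#' @param reads data frame with `sequence` and `count`.
#' @param total_mapped library total; defaults to `sum(reads$count)` when
#'   library-level totals are unavailable.
#' @param label free-text disease label.
#' @return Object of class `read_set`.
#' @export
read_set <- function(sample_id, condition = c("control", "disease"),
                     reads, total_mapped = NULL, label = "") {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  if (any(reads$count < 0)) stop("read counts must be >= 0", call. = FALSE)
  if (nrow(reads) && any(!nzchar(reads$sequence))) {
    stop("empty read sequence", call. = FALSE)
  }
  reads$sequence <- normalize_rna(reads$sequence)
  structure(list(sample_id = sample_id, condition = condition, label = label,
                 reads = reads,
                 total_mapped = total_mapped %||% sum(reads$count)),
            class = "read_set")
}

#' Read collapsed small-RNA reads from disk
#'
#' Accepts a two-column TSV (`sequence`, `count`; header optional) or a FASTA
#' file whose ids end in `-countN` (e.g. `>r1-count517`).
#'
#' @param path input file.
#' @param format `"auto"` (sniff), `"tsv"`, or `"fasta"`.
#' @return Data frame `sequence`, `count`.
#' @export
read_collapsed_reads <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("reads file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    m <- regmatches(ids, regexpr("-count[0-9]+$", ids))
    if (length(m) != length(ids)) {
      stop("FASTA read ids must end in -countN", call. = FALSE)
    }
    counts <- as.integer(sub("-count", "", m))
    return(data.frame(sequence = normalize_rna(as.character(set)),
                      count = counts, stringsAsFactors = FALSE,
                      row.names = NULL))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- !grepl("^[ACGTUacgtu]+\t[0-9]+$", first)
  tb <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tb) < 2L) stop("collapsed reads TSV needs 2 columns", call. = FALSE)
  names(tb)[1:2] <- c("sequence", "count")
  data.frame(sequence = normalize_rna(tb$sequence),
             count = as.integer(tb$count), stringsAsFactors = FALSE)
}

#' Read a sample manifest
#'
#' TSV with columns `sample_id`, `condition` (`disease`/`control`) and `path`
#' to each sample's collapsed reads.
#'
#' @param path manifest TSV.
#' @param base_dir optional directory against which relative read paths are
#'   resolved; defaults to the manifest's directory.
#' @return List of [read_set()] objects.
#' @export
read_sample_manifest <- function(path, base_dir = NULL) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "path")
  if (!all(need %in% names(tb))) {
    stop("sample manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base_dir <- base_dir %||% dirname(path)
  lapply(seq_len(nrow(tb)), function(i) {
    p <- tb$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, tb$path[i])
    read_set(tb$sample_id[i], tb$condition[i], read_collapsed_reads(p))
  })
}

#' Reads-per-million normalisation
#'
#' @param count read count(s).
#' @param total_mapped library total (> 0).
#' @return `count * 1e6 / total_mapped`.
#' @examples
#' rpm(500, 1e6) # 500
#' @export
rpm <- function(count, total_mapped) {
  if (length(total_mapped) != 1L || total_mapped <= 0) {
    stop("total_mapped must be a positive scalar", call. = FALSE)
  }
  count * 1e6 / total_mapped
}

#' Fill within-locus relative expression percentages
#'
#' `percent = 100 * count / sum(count)` over the records of one locus within
#' one sample, so percentages always total 100.
#'
#' @param records isomiR data frame with a `count` column.
#' @return The same data frame with `percent` filled; an empty data frame
#'   (with a warning) when the locus total is zero.
#' @export
locus_percentages <- function(records) {
  total <- sum(records$count)
  if (total <= 0) {
    warning("zero locus total; no percentages computed", call. = FALSE)
    return(records[0, , drop = FALSE])
  }
  records$percent <- 100 * records$count / total
  records
}

#' Extract isomiRs of one miRNA locus from a read set
#'
#' A read is assigned to the locus when, after removing the shortest 3'
#' suffix (length at most `max_tail`) that leaves an exact substring of the
#' hairpin, the remainder's start lies within `window` nt of the canonical
#' start. The removed suffix is the non-template 3' addition (`tail3`);
#' `offset5`/`offset3` are the signed template end shifts relative to the
#' canonical 5'/3' ends (negative `offset5` extends 5' of the canonical
#' start). When the remainder matches the hairpin at several places, the hit
#' closest to the canonical start is taken (ties: 5'-most). Reads matching
#' nowhere within the window are ignored.
#'
#' @param reads a [read_set()] or a data frame `sequence`, `count`.
#' @param hairpin hairpin record or RNA string.
#' @param canonical canonical mature record or RNA string (must occur on the
#'   hairpin).
#' @param window maximum distance (nt) between read start and canonical
#'   start; default 5.
#' @param max_tail maximum non-template 3' addition length; default 3.
#' @param min_length minimum templated remainder length; default 15.
#' @param locus_id label for the locus; defaults to the canonical's id.
#' @return Data frame `locus_id`, `sequence`, `offset5`, `offset3`, `tail3`,
#'   `count`, `rpm`, `percent`, sorted by decreasing count.
#' @export
extract_isomirs <- function(reads, hairpin, canonical, window = 5,
                            max_tail = 3, min_length = 15, locus_id = NULL) {
  rd <- if (inherits(reads, "read_set")) reads$reads else reads
  total <- if (inherits(reads, "read_set")) reads$total_mapped
           else sum(rd$count)
  hseq <- record_seq(hairpin)
  loc <- locate_mature(canonical, hairpin)
  cstart <- loc[["start"]]
  cend <- loc[["end"]]
  locus_id <- locus_id %||% record_id(canonical, "locus")
  if (!nrow(rd)) {
    out <- data.frame(locus_id = character(), sequence = character(),
                      offset5 = integer(), offset3 = integer(),
                      tail3 = character(), count = integer(),
                      rpm = numeric(), percent = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  # collapse duplicate sequences up front: assignment is per-sequence
  agg <- tapply(rd$count, rd$sequence, sum)
  seqs <- names(agg)
  counts <- as.integer(agg)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    for (tl in 0:max_tail) {
      if (n - tl < min_length) break
      core <- substr(s, 1L, n - tl)
      hits <- gregexpr(core, hseq, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      # minimal trimming found a template match: closest start wins, ties 5'
      hits <- as.integer(hits)
      best <- hits[order(abs(hits - cstart), hits)][1L]
      if (abs(best - cstart) <= window) {
        rows[[i]] <- data.frame(
          locus_id = locus_id, sequence = s,
          offset5 = best - cstart,
          offset3 = (best + nchar(core) - 1L) - cend,
          tail3 = substr(s, n - tl + 1L, n),
          count = counts[i], stringsAsFactors = FALSE)
      }
      break  # matched the hairpin; do not trim further
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    return(data.frame(locus_id = character(), sequence = character(),
                      offset5 = integer(), offset3 = integer(),
                      tail3 = character(), count = integer(),
                      rpm = numeric(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out$rpm <- rpm(out$count, total)
  out <- locus_percentages(out)
  out
}

#' Build a cross-sample locus profile
#'
#' Runs [extract_isomirs()] on every sample of a locus and collects the
#' per-sample isomiR tables.
#'
#' @param readsets list of [read_set()] objects.
#' @inheritParams extract_isomirs
#' @return Object of class `locus_profile`: `locus_id`, `samples` (named list
#'   of isomiR data frames), `conditions` (named character vector).
#' @export
locus_profile <- function(readsets, hairpin, canonical, window = 5,
                          max_tail = 3, min_length = 15, locus_id = NULL) {
  locus_id <- locus_id %||% record_id(canonical, "locus")
  samples <- list()
  conditions <- character()
  for (rs in readsets) {
    stopifnot(inherits(rs, "read_set"))
    samples[[rs$sample_id]] <- suppressWarnings(
      extract_isomirs(rs, hairpin, canonical, window = window,
                      max_tail = max_tail, min_length = min_length,
                      locus_id = locus_id))
    conditions[rs$sample_id] <- rs$condition
  }
  structure(list(locus_id = locus_id, samples = samples,
                 conditions = conditions),
            class = "locus_profile")
}

isomir_key <- function(df) {
  paste0(ifelse(df$offset5 >= 0, paste0("+", df$offset5), df$offset5), "/",
         ifelse(df$offset3 >= 0, paste0("+", df$offset3), df$offset3),
         ifelse(nzchar(df$tail3), paste0("+", df$tail3), ""))
}

#' Summarise isomiR expression across samples
#'
#' Samples whose locus-level RPM total is below `min_rpm` are dropped
#' (abundance filter). For each isomiR (keyed by `offset5/offset3/tail3`) the
#' mean and sample SD of the within-locus percentage are computed over the
#' retained samples, with absent-in-sample treated as 0 percent; the SD of a
#' single sample is 0. IsomiRs observed in fewer than `min_samples` samples
#' are pooled into an `"other"` row. Dominance rank 1 is the highest mean
#' percentage.
#'
#' @param profile `locus_profile`.
#' @param min_rpm minimum per-sample locus RPM; default 1.
#' @param min_samples minimum number of samples an isomiR must appear in to
#'   stay un-pooled; default 10 percent of retained samples.
#' @return Data frame of class `isomir_summary`: `key`, `offset5`, `offset3`,
#'   `tail3`, `n_samples`, `mean_percent`, `sd_percent`, `rank`; attribute
#'   `samples_used`.
#' @export
profile_summary <- function(profile, min_rpm = 1, min_samples = NULL) {
  stopifnot(inherits(profile, "locus_profile"))
  keep <- vapply(profile$samples,
                 function(df) nrow(df) > 0 && sum(df$rpm) >= min_rpm,
                 logical(1))
  samples <- profile$samples[keep]
  if (!length(samples)) stop("no sample passes the abundance filter",
                             call. = FALSE)
  min_samples <- min_samples %||% ceiling(0.1 * length(samples))
  # percent per key per sample (0 when absent)
  keyinfo <- list()
  pm <- list()
  for (sid in names(samples)) {
    df <- samples[[sid]]
    k <- isomir_key(df)
    pm[[sid]] <- setNames(df$percent, k)
    for (i in seq_along(k)) keyinfo[[k[i]]] <- df[i, c("offset5", "offset3",
                                                       "tail3")]
  }
  keys <- names(keyinfo)
  mat <- matrix(0, nrow = length(keys), ncol = length(samples),
                dimnames = list(keys, names(samples)))
  for (sid in names(samples)) mat[names(pm[[sid]]), sid] <- pm[[sid]]
  present <- rowSums(mat > 0)
  pool <- present < min_samples
  rows <- list()
  for (k in keys[!pool]) {
    v <- mat[k, ]
    rows[[k]] <- data.frame(
      key = k, offset5 = keyinfo[[k]]$offset5,
      offset3 = keyinfo[[k]]$offset3, tail3 = keyinfo[[k]]$tail3,
      n_samples = present[[k]], mean_percent = mean(v),
      sd_percent = if (length(v) > 1L) sd(v) else 0,
      stringsAsFactors = FALSE)
  }
  if (any(pool)) {
    v <- colSums(mat[pool, , drop = FALSE])
    rows[["other"]] <- data.frame(
      key = "other", offset5 = NA_integer_, offset3 = NA_integer_,
      tail3 = NA_character_, n_samples = sum(v > 0), mean_percent = mean(v),
      sd_percent = if (length(v) > 1L) sd(v) else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_percent, out$key), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "samples_used") <- names(samples)
  class(out) <- c("isomir_summary", "data.frame")
  out
}

box_stats <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  data.frame(n = length(x), q1 = q[1L], median = q[2L], q3 = q[3L],
             whisker_low = min(x[x >= lo]), whisker_high = max(x[x <= hi]))
}

#' Compare isomiR expression dispersion between disease and control
#'
#' Collects, per group, the per-isomiR SDs of the within-locus percentages
#' across samples (one SD per isomiR per locus, pooled-`"other"` rows
#' excluded), summarises each group's SD distribution as box statistics
#' (quartiles, 1.5 x IQR whiskers), and compares the two distributions with a
#' two-tailed rank-sum (Mann-Whitney) test.
#'
#' @param disease,control lists of `locus_profile`s; every profile must hold
#'   at least 2 samples.
#' @param min_rpm,min_samples passed to [profile_summary()].
#' @return List with `disease` and `control` (each: `sds`, `box`), and `test`
#'   (`W`, `p.value`).
#' @export
dispersion_compare <- function(disease, control, min_rpm = 1,
                               min_samples = NULL) {
  group_sds <- function(profiles, what) {
    if (!length(profiles)) stop("empty ", what, " group", call. = FALSE)
    sds <- numeric(0)
    for (pr in profiles) {
      if (length(pr$samples) < 2L) {
        stop(what, " profile '", pr$locus_id,
             "' has < 2 samples; SDs undefined", call. = FALSE)
      }
      # loci in which no sample passes the abundance filter carry no signal
      sm <- tryCatch(profile_summary(pr, min_rpm = min_rpm,
                                     min_samples = min_samples),
                     error = function(e) NULL)
      if (is.null(sm)) next
      sds <- c(sds, sm$sd_percent[sm$key != "other"])
    }
    if (!length(sds)) {
      stop("no ", what, " locus passes the abundance filter", call. = FALSE)
    }
    sds
  }
  dsd <- group_sds(disease, "disease")
  csd <- group_sds(control, "control")
  wt <- suppressWarnings(wilcox.test(dsd, csd, alternative = "two.sided",
                                     exact = FALSE))
  pv <- wt$p.value
  if (!is.finite(pv)) pv <- 1  # fully tied SD distributions carry no signal
  list(disease = list(sds = dsd, box = box_stats(dsd)),
       control = list(sds = csd, box = box_stats(csd)),
       test = list(W = unname(wt$statistic), p.value = pv))
}
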