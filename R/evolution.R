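# Cross-species analysis: shared miRNA families, consensus inference of
# unannotated arms, core trimming, per-position divergence against the human
# reference, and population-style diversity statistics (pi, Hd, k).

#' Normalise a mature miRNA id to member and family names
#'
#' Pure string operations, applied in order: lowercase; drop the species
#' prefix (first hyphen token); drop a legacy `*` marker; drop an `-5p`/`-3p`
#' arm suffix; drop a trailing single-digit copy number (`-1`, `-2`, ... as in
#' `let-7a-1`). The family name further strips a trailing letter variant
#' (`let-7a` -> `let-7`, `mir-30b` -> `mir-30`).
#'
#' @param ids character vector of mature ids (e.g. `"hsa-miR-30a-5p"`).
#' @return Data frame `id`, `member`, `family`.
#' @export
normalize_mirna_name <- function(ids) {
  member <- tolower(ids)
  member <- sub("^[^-]+-", "", member)      # species code
  member <- sub("\\*$", "", member)         # legacy star notation
  member <- sub("-(5p|3p)$", "", member)    # arm suffix
  member <- sub("-[0-9]$", "", member)      # copy number
  family <- sub("[a-z]+$", "", member)
  data.frame(id = ids, member = member, family = family,
             stringsAsFactors = FALSE)
}

#' Find miRNA gene families shared by all species
#'
#' Member names are normalised with [normalize_mirna_name()]; a family is
#' shared when every species contributes at least one member of it.
#'
#' @param per_species_matures named list (by species code) of mature record
#'   data frames or character id vectors.
#' @return List with `families` (character vector of shared family names) and
#'   `members` (data frame `family`, `species`, `member`, `id` restricted to
#'   shared families).
#' @export
find_shared_families <- function(per_species_matures) {
  if (length(per_species_matures) < 2L) {
    stop("need at least 2 species", call. = FALSE)
  }
  species <- names(per_species_matures)
  tabs <- lapply(species, function(sp) {
    x <- per_species_matures[[sp]]
    ids <- if (is.data.frame(x)) x$id else as.character(x)
    if (!length(ids)) {
      return(data.frame(id = character(), member = character(),
                        family = character(), species = character(),
                        stringsAsFactors = FALSE))
    }
    nm <- normalize_mirna_name(ids)
    nm$species <- sp
    nm
  })
  all <- do.call(rbind, tabs)
  fam_by_sp <- lapply(split(all$family, all$species), unique)
  shared <- Reduce(intersect, fam_by_sp[species[species %in% names(fam_by_sp)]])
  if (length(fam_by_sp) < length(species)) shared <- character(0L)
  members <- all[all$family %in% shared,
                 c("family", "species", "member", "id")]
  members <- unique(members)
  members <- members[order(members$family, members$species, members$member), ]
  rownames(members) <- NULL
  list(families = sort(shared), members = members)
}

#' Infer an unannotated mature arm from the human consensus
#'
#' Globally aligns the target hairpin to the human hairpin (free end gaps)
#' and reads off the target segment spanning the columns of the annotated
#' human mature; gaps are removed from the prediction.
#'
#' Prediction fails when the segment is shorter than 15 nt, more than half
#' gaps, less than `min_identity` identical to the human mature, or not
#' nearly colinear (more than a quarter of the window's columns carry a gap
#' on either side). Consensus inference is only meaningful while the arm is
#' conserved; the identity and colinearity guards also catch alignments that
#' absorbed a deleted arm into a cost-free terminal overhang.
#'
#' @param hairpin target-species hairpin record or RNA string.
#' @param human_hairpin,human_mature the annotated human hairpin and mature.
#' @param min_identity minimum fraction of mature positions matching the
#'   human reference; default 0.6.
#' @return Predicted mature RNA string for the target species.
#' @export
infer_missing_arm <- function(hairpin, human_hairpin, human_mature,
                              min_identity = 0.6) {
  hseq <- record_seq(human_hairpin)
  tseq <- record_seq(hairpin)
  loc <- locate_mature(human_mature, human_hairpin)
  al <- nw_align(hseq, tseq)
  ach <- strsplit(al$a, "", fixed = TRUE)[[1L]]
  bch <- strsplit(al$b, "", fixed = TRUE)[[1L]]
  colof <- cumsum(ach != "-")                   # human position at each column
  cols <- which(colof >= loc[["start"]] & colof <= loc[["end"]] & ach != "-")
  cols <- seq(min(cols), max(cols))             # contiguous segment incl. gaps
  seg <- bch[cols]
  gap_frac <- mean(seg == "-")
  indel_frac <- mean(seg == "-" | ach[cols] == "-")
  matches <- sum(ach[cols] == seg & seg != "-")
  identity <- matches / nchar(record_seq(human_mature))
  pred <- paste(seg[seg != "-"], collapse = "")
  if (nchar(pred) < 15L || gap_frac > 0.5 || identity < min_identity ||
      indel_frac > 0.25) {
    stop("arm prediction failed for ", record_id(hairpin, "<target>"),
         sprintf(
           ": aligned segment %d nt, %.0f%% gaps, %.0f%% indel columns, %.0f%% identity",
           nchar(pred), 100 * gap_frac, 100 * indel_frac, 100 * identity),
         call. = FALSE)
  }
  pred
}

#' Trim terminal gap columns from an aligned family
#'
#' Removes leading and trailing columns in which any row has a gap (terminal
#' length differences between species); internal gap columns are retained.
#' This leaves the "core" of the alignment on which divergence and diversity
#' are computed.
#'
#' @param aln `aligned_family`.
#' @return Trimmed `aligned_family`.
#' @export
trim_core <- function(aln) {
  stopifnot(inherits(aln, "aligned_family"))
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  nogap <- which(colSums(mat == "-") == 0L)
  if (!length(nogap)) stop("empty core after trimming", call. = FALSE)
  keep <- seq(min(nogap), max(nogap))
  rows <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  aln$rows <- setNames(rows, names(aln$rows))
  aln
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

#' Per-position divergence profile against the reference
#'
#' At every core column each non-reference row is compared with the reference
#' nucleotide (human by default): same purine or same pyrimidine but
#' different base is a transition, cross-class difference a transversion, a
#' gap on exactly one side an indel. `substitution_rate` is
#' `(transitions + transversions) / n_compared` per position, where
#' `n_compared` counts rows with at least one non-gap member of the pair.
#'
#' @param aln `aligned_family`, normally core-trimmed (see [trim_core()]).
#' @return Data frame of class `divergence_profile`: `position`,
#'   `transitions`, `transversions`, `indels`, `n_compared`,
#'   `substitution_rate`; attributes `reference` and `n_rows`.
#' @export
divergence_profile <- function(aln) {
  stopifnot(inherits(aln, "aligned_family"))
  if (!aln$reference %in% names(aln$rows)) {
    stop("reference row absent", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(mat) <- names(aln$rows)
  ref <- mat[aln$reference, ]
  oth <- mat[setdiff(rownames(mat), aln$reference), , drop = FALSE]
  L <- ncol(mat)
  ts <- tv <- ind <- ncmp <- integer(L)
  for (p in seq_len(L)) {
    r <- ref[p]
    col <- oth[, p]
    both_gap <- col == "-" & r == "-"
    one_gap <- xor(col == "-", r == "-")
    ncmp[p] <- sum(!both_gap)
    ind[p] <- sum(one_gap)
    cmp <- !both_gap & !one_gap & col != r
    if (any(cmp)) {
      same_class <- (r %in% PURINES & col %in% PURINES) |
                    (r %in% PYRIMIDINES & col %in% PYRIMIDINES)
      ts[p] <- sum(cmp & same_class)
      tv[p] <- sum(cmp & !same_class)
    }
  }
  out <- data.frame(position = seq_len(L), transitions = ts,
                    transversions = tv, indels = ind, n_compared = ncmp,
                    substitution_rate = ifelse(ncmp > 0, (ts + tv) / ncmp, 0))
  attr(out, "reference") <- aln$reference
  attr(out, "n_rows") <- nrow(mat)
  class(out) <- c("divergence_profile", "data.frame")
  out
}

#' Mean substitution percentage of a divergence profile
#'
#' The per-miRNA summary used as the pairing unit in arm comparisons: the
#' mean over positions of `substitution_rate`, expressed as a percentage.
#'
#' @param profile `divergence_profile`.
#' @return Numeric scalar (percent).
#' @export
mean_substitution_rate <- function(profile) {
  100 * mean(profile$substitution_rate)
}

#' Nucleotide diversity statistics of a miRNA population
#'
#' For a set of aligned sequences ("miRNA population"): `k` is the mean
#' number of pairwise differences, counting positions where both members of a
#' pair are non-gap and differ (gap-vs-gap columns contribute neither
#' differences nor comparisons); `pi = k / L` with `L` the core alignment
#' length; `Hd = n/(n-1) * (1 - sum(p_h^2))` over distinct haplotypes with
#' frequencies `p_h`. Sampling SDs follow Nei (1987): eq. 10.7 for pi (no
#' recombination) and eq. 8.12 for Hd.
#'
#' @param seqs character vector of RNA strings (may carry names); gapped and
#'   equal-length if `aligned = TRUE`.
#' @param aligned if `FALSE` (default) sequences are star-aligned around the
#'   first sequence and core-trimmed first.
#' @return Object of class `diversity_stats`: `n`, `L`, `pi`, `pi_sd`, `hd`,
#'   `hd_sd`, `k`.
#' @export
diversity_stats <- function(seqs, aligned = FALSE) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (!aligned) {
    nm <- names(seqs) %||% paste0("s", seq_len(n))
    names(seqs) <- make.unique(nm)
    aln <- star_align(seqs, reference = names(seqs)[1L])
    aln <- trim_core(aln)
    seqs <- aln$rows
  } else if (length(unique(nchar(seqs))) != 1L) {
    stop("pre-aligned sequences must have equal lengths", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  L <- ncol(mat)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- mat[i, ]; b <- mat[j, ]
      ok <- a != "-" & b != "-"
      total <- total + sum(a[ok] != b[ok])
    }
  }
  npairs <- n * (n - 1) / 2
  k <- total / npairs
  pi <- k / L
  # haplotypes: distinct aligned sequences
  p <- as.numeric(table(seqs)) / n
  sum2 <- sum(p^2)
  hd <- n / (n - 1) * (1 - sum2)
  hd_var <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum2^2) + sum2 - sum2^2)
  pi_var <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(list(n = n, L = L, pi = pi, pi_sd = sqrt(max(pi_var, 0)),
                 hd = hd, hd_sd = sqrt(max(hd_var, 0)), k = k),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(
    "Diversity: n = %d, L = %d | pi = %.4f +/- %.4f, Hd = %.4f +/- %.4f, k = %.2f\n",
    x$n, x$L, x$pi, x$pi_sd, x$hd, x$hd_sd, x$k))
  invisible(x)
}

# Wilcoxon signed-rank Z with zero-difference removal and tie correction,
# normal approximation (what Stata's signrank prints); all-zero differences
# return Z = 0, p = 1 by convention.
signed_rank_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(Z = 0, p.value = 1, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  Z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  list(Z = Z, p.value = 2 * pnorm(-abs(Z)), n = n)
}

profile_rates <- function(x) {
  if (inherits(x, "divergence_profile")) return(list(100 * x$substitution_rate))
  if (is.data.frame(x)) stop("expected divergence profile(s)", call. = FALSE)
  if (is.numeric(x)) return(as.list(x))
  if (is.list(x)) {
    return(lapply(x, function(p) {
      if (inherits(p, "divergence_profile")) 100 * p$substitution_rate
      else if (is.numeric(p) && length(p) == 1L) p  # already a mean percent
      else stop("cannot interpret divergence input", call. = FALSE)
    }))
  }
  stop("cannot interpret divergence input", call. = FALSE)
}

#' Compare divergence between the 5p and 3p arms
#'
#' Two paired two-tailed statistics: a Wilcoxon signed-rank test on per-pair
#' mean substitution percentages (one value per miRNA pair; positionwise
#' pairing across different-length miRNAs is ill-defined), and a Spearman
#' rank correlation. Given a single profile per arm, both tests operate on
#' the positionwise percentage vectors (truncated to the common length);
#' given lists of profiles (one per miRNA pair) or numeric vectors of mean
#' percentages, they operate on the per-pair means.
#'
#' @param p5,p3 `divergence_profile`, list of profiles, or numeric vector of
#'   mean substitution percentages; `p5` and `p3` must pair element-wise.
#' @return List with `wilcoxon` (`Z`, `p.value`, `n`) and `spearman` (`rho`,
#'   `p.value`).
#' @export
arm_divergence_compare <- function(p5, p3) {
  r5 <- profile_rates(p5)
  r3 <- profile_rates(p3)
  if (length(r5) == 1L && length(r3) == 1L) {
    len <- min(length(r5[[1L]]), length(r3[[1L]]))
    x <- r5[[1L]][seq_len(len)]
    y <- r3[[1L]][seq_len(len)]
  } else {
    if (length(r5) != length(r3)) {
      stop("5p and 3p inputs must pair element-wise", call. = FALSE)
    }
    x <- vapply(r5, mean, numeric(1))
    y <- vapply(r3, mean, numeric(1))
  }
  if (!length(x)) stop("empty divergence profiles", call. = FALSE)
  wil <- signed_rank_test(x, y)
  sp <- if (length(x) >= 3L && (sd(x) > 0 && sd(y) > 0)) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p.value = ct$p.value)
  } else if (sd(x) == 0 && sd(y) == 0 && all(x == y)) {
    list(rho = 1, p.value = NA_real_)   # identical profiles
  } else {
    list(rho = NA_real_, p.value = NA_real_)
  }
  list(wilcoxon = wil, spearman = sp)
}

#' Per-family, per-arm divergence from species-resolved matures
#'
#' Convenience driver: groups mature records by family and arm, star-aligns
#' each group around the reference species, trims the core and profiles the
#' divergence.
#'
#' @param matures data frame with columns `species`, `family`, `arm`,
#'   `sequence` (as produced by [generate_phylo_families()]), or a mature
#'   record data frame plus `family`/`arm` columns.
#' @param reference reference species code; default `"hsa"`.
#' @return List with `summary` (data frame: `family`, `arm`, `n_species`,
#'   `core_length`, `mean_rate_pct`) and `profiles` (named list of
#'   `divergence_profile`s, keys `family.arm`).
#' @export
family_divergence <- function(matures, reference = "hsa") {
  stopifnot(all(c("species", "family", "arm", "sequence") %in% names(matures)))
  keys <- interaction(matures$family, matures$arm, drop = TRUE)
  profiles <- list()
  rows <- list()
  for (k in levels(keys)) {
    sub <- matures[keys == k, , drop = FALSE]
    if (nrow(sub) < 2L || !reference %in% sub$species) next
    seqs <- setNames(sub$sequence, sub$species)
    aln <- trim_core(star_align(seqs, reference = reference,
                                name = sub$family[1L], arm = sub$arm[1L]))
    prof <- divergence_profile(aln)
    profiles[[k]] <- prof
    rows[[k]] <- data.frame(family = sub$family[1L], arm = sub$arm[1L],
                            n_species = nrow(sub),
                            core_length = nrow(prof),
                            mean_rate_pct = mean_substitution_rate(prof),
                            stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, profiles = profiles)
}
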