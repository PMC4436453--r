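# Seeded synthetic-data generator. It emulates the statistical structure the
# pipeline assumes -- cross-species conservation with arm-specific
# substitution pressure, and per-sample isomiR read populations with a
# dominant template, small 5'/3' end shifts, non-template 3' additions and
# condition-dependent dispersion -- so every analysis stage is testable
# without any database download. Every generator is fully deterministic
# given (config, seed) and writes/returns a truth table.

# the ten study species, human first (hsa is the root/reference haplotype)
STUDY_SPECIES <- c("hsa", "mmu", "bta", "eca", "mdo",
                   "gga", "aca", "xtr", "dre", "pma")

default_offset_probs <- function() {
  g <- expand.grid(offset5 = -2:2, offset3 = -2:2)
  g <- g[!(g$offset5 == 0 & g$offset3 == 0), ]
  w <- 2^-(abs(g$offset5) + abs(g$offset3))
  g$prob <- w / sum(w)
  rownames(g) <- NULL
  g
}

#' Build a validated synthetic-data configuration
#'
#' One object carries every generator parameter. Defaults describe the study
#' conditions the generators emulate: ten vertebrate species with the human
#' sequence as reference, ~22 nt matures on ~90 nt hairpins, a weakly
#' substituted dominant arm vs a more variable arm, a canonical isomiR at
#' 70 percent of its locus with end-variants within +/-2 nt, and
#' Dirichlet-multinomial read counts whose concentration is the dispersion
#' knob (smaller = more dispersed).
#'
#' @param seed integer RNG seed; per-generator substreams are derived from it
#'   by fixed offsets.
#' @param n_species number of species (first `n_species` of the ten study
#'   codes, extended as `sp11`, ... beyond ten).
#' @param n_families number of miRNA families to simulate.
#' @param n_partial_families how many of those are planted in only a strict
#'   subset of species (for shared-family discovery tests).
#' @param hairpin_length root hairpin length (nt).
#' @param mature_length_mean,mature_length_sd,mature_length_bounds normal
#'   length model for matures, rounded and clamped.
#' @param sub_rate_5p,sub_rate_3p per-position substitution probabilities
#'   inside the 5p / 3p mature.
#' @param background_rate substitution rate outside the matures; default
#'   `1.5 * max(sub_rate_5p, sub_rate_3p)` (non-mature hairpin sequence
#'   evolves faster).
#' @param indel_rate per-position deletion probability inside matures;
#'   default 0 (cross-species mature miRNAs diverge almost exclusively by
#'   substitution; length variation is terminal and is modelled by the
#'   hairpin end jitter). Exposed for robustness experiments.
#' @param n_samples_control,n_samples_disease samples per condition.
#' @param dominant_fraction expected within-locus percentage of the canonical
#'   isomiR (0-100, exclusive).
#' @param offset_probs data frame `offset5`, `offset3`, `prob` over the
#'   non-canonical end-shift combinations (must sum to 1); default weights
#'   `2^-(|offset5| + |offset3|)` on the \[-2, 2\] square.
#' @param tail_probability per-read probability of a non-template 3'
#'   addition.
#' @param tail_length_probs probabilities of tail lengths 1..3.
#' @param dispersion_control,dispersion_disease Dirichlet concentration per
#'   condition (> 0; smaller = more between-sample dispersion).
#' @param library_size_meanlog,library_size_sdlog lognormal model of
#'   per-locus, per-sample read totals.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_species = 10L,
                             n_families = 20L,
                             n_partial_families = 0L,
                             hairpin_length = 90L,
                             mature_length_mean = 22,
                             mature_length_sd = 1,
                             mature_length_bounds = c(20L, 24L),
                             sub_rate_5p = 0.02,
                             sub_rate_3p = 0.12,
                             background_rate = NULL,
                             indel_rate = 0,
                             n_samples_control = 20L,
                             n_samples_disease = 20L,
                             dominant_fraction = 70,
                             offset_probs = NULL,
                             tail_probability = 0.1,
                             tail_length_probs = c(0.6, 0.3, 0.1),
                             dispersion_control = 50,
                             dispersion_disease = 50,
                             library_size_meanlog = log(2e4),
                             library_size_sdlog = 0.2) {
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              n_families = as.integer(n_families),
              n_partial_families = as.integer(n_partial_families),
              hairpin_length = as.integer(hairpin_length),
              mature_length_mean = mature_length_mean,
              mature_length_sd = mature_length_sd,
              mature_length_bounds = as.integer(mature_length_bounds),
              sub_rate_5p = sub_rate_5p, sub_rate_3p = sub_rate_3p,
              background_rate = background_rate %||%
                (1.5 * max(sub_rate_5p, sub_rate_3p)),
              indel_rate = indel_rate,
              n_samples_control = as.integer(n_samples_control),
              n_samples_disease = as.integer(n_samples_disease),
              dominant_fraction = dominant_fraction,
              offset_probs = offset_probs %||% default_offset_probs(),
              tail_probability = tail_probability,
              tail_length_probs = tail_length_probs,
              dispersion_control = dispersion_control,
              dispersion_disease = dispersion_disease,
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog)
  probs <- c(cfg$sub_rate_5p, cfg$sub_rate_3p, cfg$background_rate,
             cfg$indel_rate, cfg$tail_probability, cfg$offset_probs$prob,
             cfg$tail_length_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$offset_probs$prob) - 1) > 1e-8) {
    stop("offset_probs must sum to 1", call. = FALSE)
  }
  if (cfg$dominant_fraction >= 100 || cfg$dominant_fraction <= 0) {
    stop("dominant_fraction must lie strictly between 0 and 100",
         call. = FALSE)
  }
  if (cfg$dispersion_control <= 0 || cfg$dispersion_disease <= 0) {
    stop("Dirichlet concentrations must be > 0", call. = FALSE)
  }
  if (cfg$n_species < 2L) stop("need at least 2 species", call. = FALSE)
  if (cfg$n_partial_families >= cfg$n_families) {
    stop("n_partial_families must be < n_families", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Load a synthetic configuration from YAML or JSON
#'
#' Fields mirror [synthetic_config()] arguments; omitted fields take the
#' defaults. `offset_probs` may be given as a list of
#' `{offset5, offset3, prob}` records.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `synthetic_config`.
#' @export
synthetic_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(vals$offset_probs) && !is.data.frame(vals$offset_probs)) {
    vals$offset_probs <- as.data.frame(do.call(rbind, lapply(
      vals$offset_probs, as.data.frame)))
  }
  unknown <- setdiff(names(vals), names(formals(synthetic_config)))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(synthetic_config, vals)
}

species_codes <- function(n) {
  if (n <= length(STUDY_SPECIES)) STUDY_SPECIES[seq_len(n)]
  else c(STUDY_SPECIES, sprintf("sp%02d", seq(length(STUDY_SPECIES) + 1L, n)))
}

mutate_positions <- function(chars, idx) {
  bases <- c("A", "C", "G", "U")
  vapply(idx, function(i) sample(setdiff(bases, chars[i]), 1L), character(1))
}

#' Generate cross-species miRNA families with planted divergence
#'
#' For each family a root hairpin carries an embedded 5p and 3p mature; the
#' human (`hsa`) records are the root itself, and every other species is
#' derived from it by i.i.d. per-position substitution at `sub_rate_5p`
#' inside the 5p mature, `sub_rate_3p` inside the 3p mature and
#' `background_rate` elsewhere, plus rare deletions inside matures
#' (`indel_rate`) and terminal hairpin length jitter. Designating hsa as the
#' root matches the pipeline's human-referenced divergence profile, so the
#' planted rates are recovered directly.
#'
#' @param cfg `synthetic_config`.
#' @return List with `hairpins` (data frame `species`, `id`, `family`,
#'   `sequence`), `matures` (`species`, `id`, `family`, `arm`, `hairpin_id`,
#'   `sequence`, `start`, `end`), and `truth` (`mutations` data frame and the
#'   echoed config).
#' @export
generate_phylo_families <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 101L)
  sps <- species_codes(cfg$n_species)
  bases <- c("A", "C", "G", "U")
  hp_rows <- list()
  mat_rows <- list()
  mut_rows <- list()
  fam_species <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("mir-%d", 100L + f)
    partial <- f > cfg$n_families - cfg$n_partial_families
    fam_sps <- if (partial) {
      k <- sample(seq(2L, cfg$n_species - 1L), 1L)
      c("hsa", sample(setdiff(sps, "hsa"), k - 1L))
    } else sps
    fam_species[[fam]] <- fam_sps
    lens <- pmin(pmax(round(rnorm(2L, cfg$mature_length_mean,
                                  cfg$mature_length_sd)),
                      cfg$mature_length_bounds[1L]),
                 cfg$mature_length_bounds[2L])
    H <- cfg$hairpin_length
    m5s <- 6L; m5e <- m5s + lens[1L] - 1L
    m3e <- H - 5L; m3s <- m3e - lens[2L] + 1L
    if (m3s - m5e < 4L) {
      stop("hairpin too short for two matures plus a loop; increase ",
           "hairpin_length", call. = FALSE)
    }
    root <- sample(bases, H, replace = TRUE)
    region <- rep("background", H)
    region[m5s:m5e] <- "5p"
    region[m3s:m3e] <- "3p"
    rate <- c(background = cfg$background_rate, `5p` = cfg$sub_rate_5p,
              `3p` = cfg$sub_rate_3p)[region]
    for (sp in fam_sps) {
      if (sp == "hsa") {
        chars <- root
        keep <- rep(TRUE, H)
        ext5 <- ext3 <- character(0)
      } else {
        chars <- root
        sub_idx <- which(runif(H) < rate)
        if (length(sub_idx)) {
          newch <- mutate_positions(chars, sub_idx)
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            species = sp, family = fam, position = sub_idx, type = "sub",
            region = region[sub_idx], from = chars[sub_idx], to = newch,
            stringsAsFactors = FALSE)
          chars[sub_idx] <- newch
        }
        del_idx <- which(region != "background" & runif(H) < cfg$indel_rate)
        keep <- rep(TRUE, H)
        if (length(del_idx)) {
          keep[del_idx] <- FALSE
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            species = sp, family = fam, position = del_idx, type = "del",
            region = region[del_idx], from = chars[del_idx], to = "-",
            stringsAsFactors = FALSE)
        }
        # terminal length jitter: trim or extend each hairpin end by <= 2 nt
        j5 <- sample(-2:2, 1L); j3 <- sample(-2:2, 1L)
        if (j5 < 0) keep[seq_len(-j5)] <- FALSE
        if (j3 < 0) keep[seq(H + j3 + 1L, H)] <- FALSE
        ext5 <- if (j5 > 0) sample(bases, j5, replace = TRUE) else character(0)
        ext3 <- if (j3 > 0) sample(bases, j3, replace = TRUE) else character(0)
      }
      kept <- which(keep)
      hp_seq <- paste(c(ext5, chars[kept], ext3), collapse = "")
      hp_id <- paste0(sp, "-", fam)
      hp_rows[[length(hp_rows) + 1L]] <- data.frame(
        species = sp, id = hp_id, family = fam, sequence = hp_seq,
        stringsAsFactors = FALSE)
      for (arm in c("5p", "3p")) {
        rng <- if (arm == "5p") m5s:m5e else m3s:m3e
        kept_in <- kept[kept %in% rng]
        mseq <- paste(chars[kept_in], collapse = "")
        start <- length(ext5) + sum(kept < min(rng)) + 1L
        mat_rows[[length(mat_rows) + 1L]] <- data.frame(
          species = sp, id = paste0(sp, "-miR-", sub("^mir-", "", fam),
                                    "-", arm),
          family = fam, arm = arm, hairpin_id = hp_id, sequence = mseq,
          start = start, end = start + nchar(mseq) - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows)
               else data.frame(species = character(), family = character(),
                               position = integer(), type = character(),
                               region = character(), from = character(),
                               to = character(), stringsAsFactors = FALSE)
  list(hairpins = do.call(rbind, hp_rows),
       matures = do.call(rbind, mat_rows),
       truth = list(mutations = mutations, family_species = fam_species,
                    config = cfg))
}

#' Write a synthetic phylogeny to miRBase-dialect FASTA files
#'
#' One `<species>_hairpin.fa` and `<species>_mature.fa` per species, plus
#' `truth_mutations.tsv` and `truth_coordinates.tsv`.
#'
#' @param sim result of [generate_phylo_families()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fasta <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in unique(sim$hairpins$species)) {
    write_mirna_fasta(sim$hairpins[sim$hairpins$species == sp, ],
                      file.path(dir, paste0(sp, "_hairpin.fa")))
    write_mirna_fasta(sim$matures[sim$matures$species == sp, ],
                      file.path(dir, paste0(sp, "_mature.fa")))
  }
  write.table(sim$truth$mutations,
              file.path(dir, "truth_mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$matures[, c("id", "hairpin_id", "start", "end")],
              file.path(dir, "truth_coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Derive isomiR locus definitions from a synthetic phylogeny
#'
#' Takes the human records of a [generate_phylo_families()] result and
#' returns the locus table [generate_isomir_readsets()] consumes.
#'
#' @param sim result of [generate_phylo_families()].
#' @param families optional subset of family names.
#' @return Data frame `locus_id`, `hairpin`, `start`, `end`.
#' @export
synthetic_loci <- function(sim, families = NULL) {
  m <- sim$matures[sim$matures$species == "hsa", ]
  if (!is.null(families)) m <- m[m$family %in% families, ]
  hp <- setNames(sim$hairpins$sequence, sim$hairpins$id)
  data.frame(locus_id = m$id, hairpin = unname(hp[m$hairpin_id]),
             start = m$start, end = m$end, stringsAsFactors = FALSE)
}

#' Generate per-sample isomiR read sets
#'
#' For every sample, isomiR proportions are drawn from a Dirichlet centred on
#' the template proportions -- `dominant_fraction` percent to the canonical
#' sequence, the remainder spread over templated end-shift variants per
#' `offset_probs` -- with the condition's concentration; counts are then
#' multinomial at a lognormal library size. Non-template 3' tails are
#' appended to a binomial share of each variant's reads (first tail base
#' forced to differ from the next templated hairpin base). A library size of
#' zero yields an empty read set.
#'
#' @param cfg `synthetic_config`.
#' @param loci data frame `locus_id`, `hairpin`, `start`, `end` (1-based
#'   inclusive canonical coordinates), e.g. from [synthetic_loci()].
#' @return List with `readsets` (list of [read_set()]) and `truth` (data
#'   frame of per-sample true proportions).
#' @export
generate_isomir_readsets <- function(cfg, loci) {
  stopifnot(inherits(cfg, "synthetic_config"),
            all(c("locus_id", "hairpin", "start", "end") %in% names(loci)))
  set.seed(cfg$seed + 202L)
  bases <- c("A", "C", "G", "U")
  off <- cfg$offset_probs
  p_template <- c(cfg$dominant_fraction / 100,
                  (1 - cfg$dominant_fraction / 100) * off$prob)
  o5 <- c(0L, off$offset5)
  o3 <- c(0L, off$offset3)
  plan <- data.frame(
    condition = rep(c("control", "disease"),
                    c(cfg$n_samples_control, cfg$n_samples_disease)),
    sample_id = c(sprintf("ctrl%02d", seq_len(cfg$n_samples_control)),
                  sprintf("dis%02d", seq_len(cfg$n_samples_disease))),
    stringsAsFactors = FALSE)
  readsets <- vector("list", nrow(plan))
  truth <- list()
  for (s in seq_len(nrow(plan))) {
    conc <- if (plan$condition[s] == "disease") cfg$dispersion_disease
            else cfg$dispersion_control
    rows <- list()
    for (l in seq_len(nrow(loci))) {
      hp <- loci$hairpin[l]
      cs <- loci$start[l]; ce <- loci$end[l]
      if (cs + min(o5) < 1L || ce + max(o3) > nchar(hp)) {
        stop("locus ", loci$locus_id[l],
             " leaves no margin for end-shift variants", call. = FALSE)
      }
      alpha <- conc * p_template
      g <- rgamma(length(alpha), shape = alpha)
      props <- g / sum(g)
      lib <- max(0L, round(rlnorm(1L, cfg$library_size_meanlog,
                                  cfg$library_size_sdlog)))
      counts <- if (lib > 0L) as.integer(rmultinom(1L, lib, props))
                else integer(length(props))
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = plan$sample_id[s], condition = plan$condition[s],
        locus_id = loci$locus_id[l], offset5 = o5, offset3 = o3,
        true_prop = props, count = counts, stringsAsFactors = FALSE)
      for (v in which(counts > 0L)) {
        template <- substr(hp, cs + o5[v], ce + o3[v])
        n_tail <- rbinom(1L, counts[v], cfg$tail_probability)
        if (counts[v] - n_tail > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = template, count = counts[v] - n_tail,
            stringsAsFactors = FALSE)
        }
        if (n_tail > 0L) {
          tl <- sample(seq_along(cfg$tail_length_probs), 1L,
                       prob = cfg$tail_length_probs)
          nxt <- substr(hp, ce + o3[v] + 1L, ce + o3[v] + 1L)
          first <- sample(setdiff(bases, nxt), 1L)
          rest <- if (tl > 1L) sample(bases, tl - 1L, replace = TRUE)
                  else character(0)
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = paste0(template, paste(c(first, rest), collapse = "")),
            count = n_tail, stringsAsFactors = FALSE)
        }
      }
    }
    rd <- if (length(rows)) do.call(rbind, rows)
          else data.frame(sequence = character(), count = integer(),
                          stringsAsFactors = FALSE)
    readsets[[s]] <- read_set(plan$sample_id[s], plan$condition[s], rd)
  }
  list(readsets = readsets, truth = do.call(rbind, truth))
}

#' Generate UTR sequences with planted seed-match sites
#'
#' Random-composition UTRs; independently for each seed, each UTR carries one
#' planted reverse-complement site with probability `planted_fraction`
#' (non-overlapping positions; a plant is skipped and omitted from the truth
#' table if no free slot remains).
#'
#' @param cfg `synthetic_config` (for the RNG substream).
#' @param seeds list of `seed_sequence`s (see [extract_seed()]) or character
#'   vector of 7-mers.
#' @param planted_fraction per-UTR, per-seed planting probability.
#' @param n_utrs,utr_length UTR count and length (nt).
#' @return List with `utrs` (data frame `id`, `sequence`) and `truth` (data
#'   frame `utr_id`, `source_id`, `start`).
#' @export
generate_utrs <- function(cfg, seeds, planted_fraction, n_utrs = 100L,
                          utr_length = 300L) {
  stopifnot(inherits(cfg, "synthetic_config"), length(seeds) >= 1L)
  set.seed(cfg$seed + 303L)
  if (inherits(seeds, "seed_sequence")) seeds <- list(seeds)
  seed_chr <- vapply(seeds, function(s) {
    if (inherits(s, "seed_sequence")) s$seed else normalize_rna(s)
  }, character(1))
  ids <- vapply(seq_along(seeds), function(i) {
    s <- seeds[[i]]
    if (inherits(s, "seed_sequence") && !is.na(s$source_id %||% NA))
      s$source_id else paste0("seed", i)
  }, character(1))
  sites <- rna_revcomp(seed_chr)
  utr_seq <- random_rna(n_utrs, utr_length)
  truth <- list()
  for (u in seq_len(n_utrs)) {
    occupied <- integer(0)  # starts of planted sites
    for (k in seq_along(sites)) {
      if (runif(1) >= planted_fraction) next
      avail <- setdiff(seq_len(utr_length - 6L),
                       unlist(lapply(occupied, function(s) (s - 6L):(s + 6L))))
      if (!length(avail)) next
      pos <- if (length(avail) == 1L) avail else sample(avail, 1L)
      substr(utr_seq[u], pos, pos + 6L) <- sites[k]
      occupied <- c(occupied, pos)
      truth[[length(truth) + 1L]] <- data.frame(
        utr_id = sprintf("utr%04d", u), source_id = ids[k], start = pos,
        stringsAsFactors = FALSE)
    }
  }
  list(utrs = data.frame(id = sprintf("utr%04d", seq_len(n_utrs)),
                         sequence = utr_seq, stringsAsFactors = FALSE),
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(utr_id = character(), source_id = character(),
                               start = integer(), stringsAsFactors = FALSE))
}
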