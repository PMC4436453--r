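# the synthetic-data generators: determinism, degenerate limits, and
# recovery of the planted parameters by the analysis pipeline

test_that("configuration validates probabilities and sizes", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(sub_rate_5p = 1.2), "probabilities")
  expect_error(synthetic_config(dominant_fraction = 100), "between 0 and 100")
  expect_error(synthetic_config(dispersion_control = 0), "> 0")
  expect_error(synthetic_config(n_species = 1), "2 species")
  op <- default_probs <- synthetic_config()$offset_probs
  expect_equal(sum(op$prob), 1)
  op$prob <- op$prob * 2
  expect_error(synthetic_config(offset_probs = op), "sum to 1")
})

test_that("configs load from YAML and JSON files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "n_families: 3", "sub_rate_3p: 0.2"), yml)
  cfg <- synthetic_config_from_file(yml)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$n_families, 3L)
  expect_equal(cfg$sub_rate_3p, 0.2)
  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"seed": 4, "dominant_fraction": 60}', jsn)
  expect_equal(synthetic_config_from_file(jsn)$dominant_fraction, 60)
  writeLines("bogus_field: 1", yml)
  expect_error(synthetic_config_from_file(yml), "unknown config")
})

test_that("generation is fully deterministic given (config, seed)", {
  cfg <- synthetic_config(seed = 33, n_families = 4, n_species = 4)
  a <- generate_phylo_families(cfg)
  b <- generate_phylo_families(cfg)
  expect_identical(a$hairpins, b$hairpins)
  expect_identical(a$matures, b$matures)
  expect_identical(a$truth$mutations, b$truth$mutations)
  loci <- synthetic_loci(a, families = "mir-101")
  r1 <- generate_isomir_readsets(cfg, loci)
  r2 <- generate_isomir_readsets(cfg, loci)
  expect_identical(r1$readsets[[1]]$reads, r2$readsets[[1]]$reads)
  expect_identical(r1$truth, r2$truth)
  u1 <- generate_utrs(cfg, list(extract_seed(strrep("ACGU", 6))), 0.5)
  u2 <- generate_utrs(cfg, list(extract_seed(strrep("ACGU", 6))), 0.5)
  expect_identical(u1$utrs, u2$utrs)
  # FASTA on disk is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_fasta(a, d1)
  write_synthetic_fasta(b, d2)
  f <- "hsa_mature.fa"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # a different seed changes the data
  c2 <- generate_phylo_families(synthetic_config(seed = 34, n_families = 4,
                                                 n_species = 4))
  expect_false(identical(a$hairpins$sequence, c2$hairpins$sequence))
})

test_that("zero substitution rates give identical matures and zero diversity", {
  cfg <- synthetic_config(seed = 35, n_families = 3, n_species = 6,
                          sub_rate_5p = 0, sub_rate_3p = 0,
                          background_rate = 0, indel_rate = 0)
  sim <- generate_phylo_families(cfg)
  for (fam in unique(sim$matures$family)) {
    for (arm in c("5p", "3p")) {
      seqs <- sim$matures$sequence[sim$matures$family == fam &
                                     sim$matures$arm == arm]
      expect_length(unique(seqs), 1L)
      ds <- diversity_stats(seqs, aligned = TRUE)
      expect_equal(ds$pi, 0)
      expect_equal(ds$hd, 0)
    }
  }
  expect_equal(nrow(sim$truth$mutations[sim$truth$mutations$type == "sub", ]),
               0L)
})

test_that("planted coordinates and mutations are internally consistent", {
  cfg <- synthetic_config(seed = 36, n_families = 5, n_species = 5,
                          indel_rate = 0.01)
  sim <- generate_phylo_families(cfg)
  # every mature sequence sits at its recorded hairpin coordinates
  for (i in seq_len(nrow(sim$matures))) {
    m <- sim$matures[i, ]
    hp <- sim$hairpins$sequence[sim$hairpins$id == m$hairpin_id]
    expect_equal(substr(hp, m$start, m$end), m$sequence)
  }
  # partial families restrict the species set
  cfg <- synthetic_config(seed = 37, n_families = 6, n_species = 6,
                          n_partial_families = 3)
  sim <- generate_phylo_families(cfg)
  n_sp <- tapply(sim$matures$species, sim$matures$family,
                 function(x) length(unique(x)))
  expect_equal(sum(n_sp < 6), 3L)
  expect_true(all(vapply(sim$truth$family_species, function(x)
    "hsa" %in% x, logical(1))))
})

test_that("planted substitution rates are recovered by the pipeline", {
  cfg <- synthetic_config(seed = 38, n_families = 25, n_species = 10,
                          sub_rate_5p = 0.02, sub_rate_3p = 0.15)
  sim <- generate_phylo_families(cfg)
  fd <- family_divergence(sim$matures)
  pooled <- function(arm) {
    ps <- fd$profiles[fd$summary$arm == arm]
    num <- sum(vapply(ps, function(p) sum(p$transitions + p$transversions),
                      numeric(1)))
    den <- sum(vapply(ps, function(p) sum(p$n_compared), numeric(1)))
    c(est = num / den, n = den)
  }
  for (arm in c("5p", "3p")) {
    s <- if (arm == "5p") 0.02 else 0.15
    p <- pooled(arm)
    expect_lt(abs(p[["est"]] - s), 3 * sqrt(s * (1 - s) / p[["n"]]))
  }
})

test_that("a near-degenerate Dirichlet reproduces the template proportions", {
  cfg <- synthetic_config(seed = 39, dispersion_control = 1e6,
                          dispersion_disease = 1e6, tail_probability = 0,
                          n_samples_control = 3, n_samples_disease = 0,
                          library_size_meanlog = log(5e4))
  sim <- generate_phylo_families(synthetic_config(seed = 39, n_families = 1,
                                                  n_species = 2))
  loci <- synthetic_loci(sim)[1, ]
  gen <- generate_isomir_readsets(cfg, loci)
  hp <- data.frame(id = loci$locus_id, sequence = loci$hairpin)
  canonical <- data.frame(id = loci$locus_id,
                          sequence = substr(loci$hairpin, loci$start,
                                            loci$end))
  for (rs in gen$readsets) {
    iso <- extract_isomirs(rs, hp, canonical)
    canon_pct <- iso$percent[iso$offset5 == 0 & iso$offset3 == 0 &
                               iso$tail3 == ""]
    expect_equal(canon_pct, 70, tolerance = 1 / 70) # within 1 point
    expect_equal(sum(iso$percent), 100)
    # extraction recovers every generated read (all are templated here)
    expect_equal(sum(iso$count), sum(rs$reads$count))
  }
})

test_that("a zero library size yields an empty read set", {
  cfg <- synthetic_config(seed = 40, n_samples_control = 2,
                          n_samples_disease = 0,
                          library_size_meanlog = -20)
  sim <- generate_phylo_families(synthetic_config(seed = 40, n_families = 1,
                                                  n_species = 2))
  gen <- generate_isomir_readsets(cfg, synthetic_loci(sim)[1, ])
  expect_equal(nrow(gen$readsets[[1]]$reads), 0L)
  loci <- synthetic_loci(sim)[1, ]
  expect_warning(
    out <- extract_isomirs(gen$readsets[[1]],
                           data.frame(id = "h", sequence = loci$hairpin),
                           data.frame(id = "m",
                                      sequence = substr(loci$hairpin,
                                                        loci$start,
                                                        loci$end))),
    NA)
  expect_equal(nrow(out), 0L)
})

test_that("planted UTR sites appear at the planted rate", {
  cfg <- synthetic_config(seed = 41)
  seed <- extract_seed("UGAGGUAGUAGGUUGUAUAGUU", id = "let7")
  # planted_fraction 1: every UTR is a target
  gen <- generate_utrs(cfg, list(seed), planted_fraction = 1, n_utrs = 50,
                       utr_length = 250)
  ts <- scan_targets(seed, gen$utrs)
  expect_equal(length(ts$utr_ids), 50L)
  # planted_fraction 0: background matches only, within 3 sigma of the
  # closed-form per-UTR probability 1 - (1 - 4^-7)^(L - 6)
  gen0 <- generate_utrs(cfg, list(seed), planted_fraction = 0, n_utrs = 400,
                        utr_length = 300)
  ts0 <- scan_targets(seed, gen0$utrs)
  p_bg <- 1 - (1 - 4^-7)^(300 - 6)
  expect_lt(abs(length(ts0$utr_ids) - 400 * p_bg),
            3 * sqrt(400 * p_bg * (1 - p_bg)) + 1)
  expect_equal(nrow(gen0$truth), 0L)
})
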