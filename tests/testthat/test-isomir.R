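# isomiR extraction, RPM, within-locus percentages, summaries, dispersion

# deterministic locus: 19-nt prefix, 22-nt canonical, known continuation
make_locus <- function() {
  prefix <- "GGCAUCGAUGGCAUCGAUG"                 # 19 nt
  canonical <- "UGAGGUAGUAGGUUGUAUAGUU"           # 22 nt, at 20..41
  suffix <- "GUCCAUGCAUCGGAUCCAAG"                # hairpin continues with GU
  hp <- paste0(prefix, canonical, suffix)
  list(hairpin = data.frame(id = "hsa-mir-t", sequence = hp),
       canonical = data.frame(id = "hsa-miR-t-5p", sequence = canonical),
       hp = hp, cs = 20L, ce = 41L)
}

test_that("rpm is exact, linear and scale-invariant", {
  expect_equal(rpm(500, 1e6), 500)
  expect_equal(rpm(0, 123), 0)
  expect_equal(rpm(3, 12), 250000) # 3e6/12
  expect_equal(rpm(10, 100), rpm(20, 200))
  expect_equal(rpm(2 * 7, 1000), 2 * rpm(7, 1000))
  expect_error(rpm(1, 0), "positive")
})

test_that("locus percentages always total 100", {
  df <- data.frame(count = c(60, 30, 10))
  expect_equal(locus_percentages(df)$percent, c(60, 30, 10))
  expect_equal(locus_percentages(data.frame(count = 5))$percent, 100)
  df <- locus_percentages(data.frame(count = c(1, 1, 1)))
  expect_equal(df$percent, rep(100 / 3, 3))
  expect_equal(sum(df$percent), 100)
  expect_warning(out <- locus_percentages(data.frame(count = integer(0))),
                 "zero locus total")
  expect_equal(nrow(out), 0L)
})

test_that("reads map to offsets and non-template tails", {
  lc <- make_locus()
  shifted <- substr(lc$hp, lc$cs + 1, lc$ce + 1)   # offset5 +1, offset3 +1
  ext5 <- substr(lc$hp, lc$cs - 2, lc$ce)          # offset5 -2
  tailed <- paste0(lc$canonical$sequence, "AA")    # hairpin continues GU
  rs <- make_reads(c(lc$canonical$sequence, shifted, ext5, tailed,
                     strrep("CGAU", 6)),            # matches nowhere
                   c(50, 20, 10, 20, 5))
  iso <- extract_isomirs(rs, lc$hairpin, lc$canonical)
  expect_equal(nrow(iso), 4L) # foreign read ignored
  canon <- iso[iso$offset5 == 0 & iso$offset3 == 0 & iso$tail3 == "", ]
  expect_equal(canon$count, 50L)
  expect_equal(iso$offset3[iso$offset5 == 1], 1L)
  expect_equal(iso$offset5[iso$sequence == ext5], -2L)
  tl <- iso[iso$tail3 == "AA", ]
  expect_equal(tl$offset3, 0L)
  expect_equal(tl$offset5, 0L)
  # percentages over assigned reads sum to 100; rpm uses the full library
  expect_equal(sum(iso$percent), 100)
  expect_equal(iso$rpm, iso$count * 1e6 / 105)
  expect_equal(sum(iso$count), 100L)
})

test_that("extraction is order-independent and idempotent", {
  lc <- make_locus()
  seqs <- c(lc$canonical$sequence, substr(lc$hp, lc$cs + 1, lc$ce),
            paste0(lc$canonical$sequence, "C"))
  counts <- c(30, 10, 5)
  a <- extract_isomirs(make_reads(seqs, counts), lc$hairpin, lc$canonical)
  perm <- c(3, 1, 2)
  b <- extract_isomirs(make_reads(seqs[perm], counts[perm]), lc$hairpin,
                       lc$canonical)
  expect_equal(a, b)
  # duplicated rows of the same sequence are pooled
  d <- extract_isomirs(make_reads(c(seqs, seqs[1]), c(counts, 7)),
                       lc$hairpin, lc$canonical)
  expect_equal(d$count[d$offset5 == 0 & d$tail3 == ""], 37L)
})

test_that("reads outside the start window are not assigned", {
  lc <- make_locus()
  far <- substr(lc$hp, lc$cs + 8, lc$ce + 8)
  near <- substr(lc$hp, lc$cs + 4, lc$ce + 4)
  iso <- extract_isomirs(make_reads(c(far, near), c(5, 5)), lc$hairpin,
                         lc$canonical, window = 5)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$offset5, 4L)
  expect_error(extract_isomirs(make_reads("ACGU", 1),
                               lc$hairpin,
                               data.frame(id = "x", sequence = "ACGUACGUACGUACGU")),
               "not found")
})

test_that("collapsed reads round-trip through TSV and FASTA", {
  df <- data.frame(sequence = c("ACGUACGUACGUACG", "UGAGGUAGUAGGUUG"),
                   count = c(10L, 3L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_collapsed_reads(tsv), df)
  # headerless
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_collapsed_reads(tsv), df)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1-count10", df$sequence[1], ">r2-count3", df$sequence[2]),
             fa)
  expect_equal(read_collapsed_reads(fa), df)
})

test_that("profile summaries average percentages across samples", {
  lc <- make_locus()
  shifted <- substr(lc$hp, lc$cs + 1, lc$ce)
  # isomiR at 40% in sample 1, 60% in sample 2
  rs1 <- make_reads(c(lc$canonical$sequence, shifted), c(60, 40), "s1")
  rs2 <- make_reads(c(lc$canonical$sequence, shifted), c(40, 60), "s2")
  pr <- locus_profile(list(rs1, rs2), lc$hairpin, lc$canonical)
  sm <- profile_summary(pr, min_rpm = 0, min_samples = 1)
  row <- sm[sm$offset5 == 1 & !is.na(sm$offset5), ]
  expect_equal(row$mean_percent, 50)
  expect_equal(row$sd_percent, sd(c(40, 60))) # 14.142
  expect_equal(sm$rank, seq_len(nrow(sm)))
  # single sample -> SD 0 everywhere
  pr1 <- locus_profile(list(rs1), lc$hairpin, lc$canonical)
  sm1 <- profile_summary(pr1, min_rpm = 0, min_samples = 1)
  expect_true(all(sm1$sd_percent == 0))
  # rare isomiRs pool into "other"
  rs3 <- make_reads(c(lc$canonical$sequence, shifted,
                      paste0(lc$canonical$sequence, "A")),
                    c(80, 15, 5), "s3")
  pr <- locus_profile(list(rs1, rs2, rs3), lc$hairpin, lc$canonical)
  sm <- profile_summary(pr, min_rpm = 0, min_samples = 2)
  expect_true("other" %in% sm$key)
  expect_false(any(grepl("\\+A$", sm$key)))
})

test_that("the abundance filter drops sparse samples", {
  lc <- make_locus()
  rs1 <- make_reads(lc$canonical$sequence, 1000, "deep")
  rs2 <- read_set("shallow", "control",
                  data.frame(sequence = lc$canonical$sequence, count = 1L),
                  total_mapped = 1e7) # rpm 0.1 < 1
  pr <- locus_profile(list(rs1, rs2), lc$hairpin, lc$canonical)
  sm <- profile_summary(pr, min_rpm = 1, min_samples = 1)
  expect_equal(attr(sm, "samples_used"), "deep")
  expect_error(profile_summary(locus_profile(list(rs2), lc$hairpin,
                                             lc$canonical)),
               "abundance filter")
})

test_that("dispersion comparison contrasts SD distributions", {
  lc <- make_locus()
  shifted <- substr(lc$hp, lc$cs + 1, lc$ce)
  mk <- function(p, sid, cond) {
    make_reads(c(lc$canonical$sequence, shifted), c(100 - p, p), sid, cond)
  }
  stable <- locus_profile(list(mk(30, "c1", "control"),
                               mk(31, "c2", "control"),
                               mk(29, "c3", "control")),
                          lc$hairpin, lc$canonical)
  wild <- locus_profile(list(mk(10, "d1", "disease"),
                             mk(50, "d2", "disease"),
                             mk(30, "d3", "disease")),
                        lc$hairpin, lc$canonical)
  res <- dispersion_compare(list(wild), list(stable), min_rpm = 0,
                            min_samples = 1)
  expect_gt(res$disease$box$median, res$control$box$median)
  expect_true(all(c("q1", "median", "q3", "whisker_low", "whisker_high")
                  %in% names(res$disease$box)))
  # identical groups -> identical boxes, p in the no-signal region
  same <- dispersion_compare(list(stable), list(stable), min_rpm = 0,
                             min_samples = 1)
  expect_equal(same$disease$box, same$control$box)
  expect_gt(same$test$p.value, 0.9)
  # degenerate single-isomiR loci: every SD of the 100% profile is 0
  mono <- locus_profile(list(make_reads(lc$canonical$sequence, 10, "m1"),
                             make_reads(lc$canonical$sequence, 20, "m2")),
                        lc$hairpin, lc$canonical)
  res <- dispersion_compare(list(mono), list(mono), min_rpm = 0,
                            min_samples = 1)
  expect_true(all(res$disease$sds == 0))
  # < 2 samples is an error
  one <- locus_profile(list(mk(30, "x", "disease")), lc$hairpin,
                       lc$canonical)
  expect_error(dispersion_compare(list(one), list(stable)), "2 samples")
})
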