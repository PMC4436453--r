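# shared fixture builders: everything is generated in code at test time

BASES <- c("A", "C", "G", "U")

rand_rna <- function(len) paste(sample(BASES, len, replace = TRUE),
                                collapse = "")

# a hairpin with two planted matures; returns records plus coordinates
make_hairpin_pair <- function(num, species = "hsa", hp_len = 80,
                              m5 = c(6, 27), m3 = c(50, 71)) {
  hp <- rand_rna(hp_len)
  hp_id <- sprintf("%s-mir-%d", species, num)
  list(
    hairpin = data.frame(id = hp_id, accession = "", species = species,
                         sequence = hp, length = hp_len,
                         stringsAsFactors = FALSE),
    mature_5p = data.frame(id = sprintf("%s-miR-%d-5p", species, num),
                           accession = "", species = species,
                           sequence = substr(hp, m5[1], m5[2]),
                           length = m5[2] - m5[1] + 1L,
                           stringsAsFactors = FALSE),
    mature_3p = data.frame(id = sprintf("%s-miR-%d-3p", species, num),
                           accession = "", species = species,
                           sequence = substr(hp, m3[1], m3[2]),
                           length = m3[2] - m3[1] + 1L,
                           stringsAsFactors = FALSE),
    m5 = m5, m3 = m3)
}

write_fasta_tmp <- function(records, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = env)
  write_mirna_fasta(records, path)
  path
}

# brute-force oracle: diversity statistics by direct enumeration
oracle_diversity <- function(seqs) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  L <- ncol(mat)
  diffs <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      diffs <- c(diffs, sum(mat[i, ok] != mat[j, ok]))
    }
  }
  k <- mean(diffs)
  p <- as.numeric(table(seqs)) / n
  list(k = k, pi = k / L, hd = n / (n - 1) * (1 - sum(p^2)))
}

# brute-force oracle: total reference mismatches (both non-gap) in a family
oracle_ref_mismatches <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(mat) <- names(aln$rows)
  ref <- mat[aln$reference, ]
  oth <- mat[setdiff(rownames(mat), aln$reference), , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(oth))) {
    ok <- ref != "-" & oth[i, ] != "-"
    total <- total + sum(ref[ok] != oth[i, ok])
  }
  total
}

# small synthetic readset for one locus
make_reads <- function(seqs, counts, sample_id = "s1",
                       condition = "control") {
  read_set(sample_id, condition,
           data.frame(sequence = seqs, count = counts,
                      stringsAsFactors = FALSE))
}
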