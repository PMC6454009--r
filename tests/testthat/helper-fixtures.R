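# Shared helpers: small in-code fixtures written to per-test temp files.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

write_mut_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_psam <- function(M = 6, name = "R") psam(name, matrix(rnorm(M * 4), M, 4))

# naive occupancy oracle, written independently of the package's scanner:
# direct double loop over windows and motif positions, lookup by base name
naive_occupancy <- function(seq, w, mu, both = TRUE) {
  M <- nrow(w)
  colnames(w) <- c("A", "C", "G", "T")
  one <- function(s) {
    bases <- strsplit(s, "")[[1L]]
    tot <- 0
    for (i in seq_len(length(bases) - M + 1L)) {
      win <- bases[i:(i + M - 1L)]
      if (any(!win %in% colnames(w))) next
      E <- 0
      for (j in seq_len(M)) E <- E + unname(w[j, win[[j]]])
      tot <- tot + 1 / (1 + exp(E - mu))
    }
    tot
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(seq, "")[[1L]]]), collapse = "")
  one(seq) + if (both) one(rc) else 0
}

# tiny genome + mutation cohort used across hotspot/background tests
tiny_cohort <- function(seed = 1, chrom_len = 6000) {
  set.seed(seed)
  genome <- structure(c(chr1 = rand_seq(chrom_len)), class = "genome")
  list(genome = genome)
}
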