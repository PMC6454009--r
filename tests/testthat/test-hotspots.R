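region_df <- function(chrom = "chr1", start = 0, end = 1000, name = "geneA",
                      strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

mut_df <- function(pos, patient, ref = "A", alt = "G", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             patient = patient, stringsAsFactors = FALSE)
}

test_that("clustered recurrent mutations form one hotspot, lone ones do not", {
  mu <- mut_df(c(101, 103, 106, 501), c("P1", "P2", "P3", "P4"))
  hs <- find_hotspots(mu, region_df(), max_gap = 30, min_mutations = 3,
                      min_patients = 2, flank = 0)
  expect_length(hs, 1L)
  expect_equal(hs[[1]]$region$start, 100)  # 0-based of 1-based pos 101
  expect_equal(hs[[1]]$region$end, 106)
  expect_equal(hs[[1]]$n_patients, 3L)
  expect_equal(nrow(hs[[1]]$mutations), 3L)
})

test_that("patient and mutation thresholds are enforced exactly", {
  mu <- mut_df(c(101, 103, 106, 501), c("P1", "P2", "P3", "P4"))
  expect_length(find_hotspots(mu, region_df(), min_mutations = 3,
                              min_patients = 4, flank = 0), 0L)
  # 10 mutations from a single patient never form a hotspot
  solo <- mut_df(200 + 0:9, "P1")
  expect_length(find_hotspots(solo, region_df(), min_mutations = 2,
                              min_patients = 2, flank = 0), 0L)
})

test_that("flank extends hotspot regions but clips at the promoter boundary", {
  mu <- mut_df(c(11, 13), c("P1", "P2"))
  hs <- find_hotspots(mu, region_df(start = 0, end = 100), flank = 25)
  expect_equal(hs[[1]]$region$start, 0)   # 10 - 25 clipped to 0
  expect_equal(hs[[1]]$region$end, 38)    # 13 + 25
})

test_that("clustering is invariant to the order of input mutations", {
  set.seed(14)
  mu <- mut_df(sample(c(101:110, 300:305, 700)), rep(c("P1", "P2", "P3"), length.out = 17))
  hs1 <- find_hotspots(mu, region_df())
  hs2 <- find_hotspots(mu[sample(nrow(mu)), ], region_df())
  expect_equal(hs1, hs2)
})

test_that("overlapping promoter regions merge before clustering", {
  regs <- rbind(region_df(start = 0, end = 600, name = "geneA"),
                region_df(start = 500, end = 1200, name = "geneB"))
  mu <- mut_df(c(590, 610), c("P1", "P2"))  # spans the overlap
  hs <- find_hotspots(mu, regs, max_gap = 30, flank = 0)
  expect_length(hs, 1L)
  expect_match(hs[[1]]$nearest_gene, "geneA")
  expect_match(hs[[1]]$nearest_gene, "geneB")
})

test_that("reported hotspots always satisfy the configured thresholds", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    mu <- mut_df(sample(1000, n, replace = TRUE),
                 sample(paste0("P", 1:6), n, TRUE))
    mu <- mu[!duplicated(mu[, c("pos", "patient")]), ]
    mm <- sample(2:4, 1); mp <- sample(2:3, 1)
    hs <- find_hotspots(mu, region_df(), max_gap = 10, min_mutations = mm,
                        min_patients = mp, flank = 5)
    for (h in hs) {
      expect_gte(nrow(h$mutations), mm)
      expect_gte(h$n_patients, mp)
      expect_true(all(h$mutations$pos - 1 >= h$region$start &
                        h$mutations$pos - 1 < h$region$end))
      expect_equal(h$n_patients, length(unique(h$mutations$patient)))
    }
  }
})

test_that("blocks carry per-patient alternates differing at exactly the SNVs", {
  g <- structure(c(chr1 = paste0(strrep("T", 100), "AACGTT", strrep("T", 100))),
                 class = "genome")
  # hotspot covering the AACGTT island at 0-based 100..106
  mu <- rbind(mut_df(103, "P1", ref = "C", alt = "G"),
              mut_df(c(102, 105), c("P2", "P2"), ref = c("A", "T"),
                     alt = c("T", "A")))
  hs <- find_hotspots(mu, region_df(end = 206), max_gap = 30,
                      min_mutations = 2, min_patients = 2, flank = 0)
  # widen to the island for a readable check
  hs[[1]]$region$start <- 100; hs[[1]]$region$end <- 106
  blocks <- build_blocks(hs, g)
  b <- blocks[[1]]
  expect_equal(b$ref_seq, "AACGTT")
  expect_equal(b$alt_seqs[["P1"]], "AAGGTT")
  diffs <- which(strsplit(b$alt_seqs[["P2"]], "")[[1]] !=
                   strsplit(b$ref_seq, "")[[1]])
  expect_equal(diffs, c(2L, 5L))
})

test_that("conflicting alt alleles for one patient at one position abort", {
  g <- structure(c(chr1 = strrep("ACGT", 60)), class = "genome")
  mu <- rbind(mut_df(101, "P1", ref = "A", alt = "G"),
              mut_df(101, "P1", ref = "A", alt = "T"),
              mut_df(105, "P2", ref = "A", alt = "C"))
  hs <- find_hotspots(mu, region_df(), max_gap = 30, flank = 0)
  expect_error(build_blocks(hs, g), "inconsistency")
})

test_that("one alternate per mutated patient, none for the others", {
  g <- tiny_cohort(2)$genome
  pats <- paste0("P", 1:14)
  mu <- mut_df(200 + seq_along(pats),
               pats,
               ref = substring(g[["chr1"]], 200 + seq_along(pats),
                               200 + seq_along(pats)),
               alt = "N")  # placeholder, fixed below
  mu$alt <- vapply(mu$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  hs <- find_hotspots(mu, region_df(end = 1000), max_gap = 30, flank = 10)
  blocks <- build_blocks(hs, g)
  expect_equal(sort(names(blocks[[1]]$alt_seqs)), sort(pats))
  expect_true(all(nchar(unlist(blocks[[1]]$alt_seqs)) == nchar(blocks[[1]]$ref_seq)))
})

test_that("implanted fixture clusters are recovered exactly at low background", {
  d <- withr::local_tempdir()
  fx <- make_fixture(fixture_preset("recovery", seed = 42), d)
  g <- read_genome_fasta(fx$genome)
  mu <- read_mutations(fx$mutations, g)
  regions <- promoter_regions(fx$annotation, 2000, 100, g)
  hs <- find_hotspots(mu, regions)
  truth <- fx$truth_df
  # every implanted cluster is found, attributed to the right gene
  for (i in seq_len(nrow(truth))) {
    hit <- vapply(hs, function(h) {
      grepl(truth$gene[i], h$nearest_gene) &&
        h$region$start <= truth$motif_start[i] &&
        h$region$end >= truth$motif_end[i]
    }, logical(1))
    expect_equal(sum(hit), 1L)
  }
})
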