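test_that("PSAM flat files round-trip and malformed ones are rejected", {
  set.seed(1)
  pm <- psam("FOXD3", matrix(rnorm(28), 7, 4), source = "fix")
  p <- tempfile(fileext = ".psam")
  write_psam(pm, p)
  back <- read_psam(p)
  expect_equal(back$tf_name, "FOXD3")
  expect_equal(back$matrix, pm$matrix, tolerance = 1e-9)
  writeLines(c("1 2 3 4", "5 6 7 8"), p)
  expect_error(read_psam(p), "#TF")
  d <- tempfile()
  dir.create(d)
  write_psam(pm, file.path(d, "a.psam"))
  write_psam(psam("ELK1", matrix(0, 5, 4)), file.path(d, "b.psam"))
  col <- read_psam_collection(d)
  expect_setequal(names(col), c("FOXD3", "ELK1"))
  expect_error(psam("X", matrix(0, 3, 4)), "at least 4")
  expect_error(psam("X", matrix(Inf, 4, 4)), "finite")
})

test_that("binding energy sums PSAM entries and flags N windows", {
  p0 <- psam("Z", matrix(0, 4, 4))
  expect_equal(binding_energy("ACGT", p0), 0)
  p1 <- psam("O", matrix(1, 4, 4))
  expect_equal(binding_energy("TTTT", p1), 4)
  w <- rbind(c(1, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 3, 0), c(0, 0, 0, 4))
  expect_equal(binding_energy("ACGT", psam("D", w)), 10)
  expect_equal(binding_energy("ACNT", psam("D", w)), Inf)
  expect_error(binding_energy("ACG", psam("D", w)), "length")
})

test_that("zero-PSAM occupancy matches the closed form (N - M + 1)/2 at mu 0", {
  p0 <- psam("Z", matrix(0, 4, 4))
  s <- strrep("ACGT", 3)  # 12 bp, 9 windows
  expect_equal(binding_probability(s, p0, 0, strand = "forward"), 4.5)
  expect_equal(binding_probability_fast(s, p0, 0, strand = "forward"), 4.5)
  expect_equal(binding_probability_fast(s, p0, 0, strand = "both"), 9)
})

test_that("fast scanner equals the naive double-loop oracle", {
  set.seed(11)
  for (i in 1:100) {
    M <- sample(4:12, 1)
    w <- matrix(rnorm(M * 4, sd = 2), M, 4)
    s <- rand_seq(sample(M:80, 1))
    mu <- runif(1, -20, 2)
    both <- i %% 2 == 0
    strand <- if (both) "both" else "forward"
    fast <- binding_probability_fast(s, psam("R", w), mu, strand)
    oracle <- naive_occupancy(s, w, mu, both)
    expect_lt(abs(fast - oracle) / max(abs(oracle), 1), 1e-10)
  }
})

test_that("N-containing windows contribute zero occupancy", {
  w <- matrix(-1, 4, 4)
  s <- "ACGTNACGT"  # N kills every window overlapping position 5
  fast <- binding_probability_fast(s, psam("R", w), -2, "forward")
  oracle <- naive_occupancy(s, w, -2, both = FALSE)
  expect_equal(fast, oracle)
  expect_equal(fast, 2 / (1 + exp(-4 + 2)))  # only 2 N-free windows
})

test_that("long sequences scan quickly and agree with per-window terms", {
  set.seed(19)
  pm <- rand_psam(12)
  s <- rand_seq(1e5)
  mu <- -13
  t0 <- Sys.time()
  total <- binding_probability_fast(s, pm, mu, "forward")
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  # spot-check: 10 random windows' logistic terms computed independently
  # never exceed the total, and removing them from the sum is consistent
  idx <- sample(1e5 - 11, 10)
  terms <- vapply(idx, function(i)
    1 / (1 + exp(binding_energy(substr(s, i, i + 11), pm) - mu)), 0)
  expect_true(all(terms >= 0 & terms <= 1))
  expect_gte(total, sum(terms) - 1e-9)
})

test_that("occupancy is monotone non-decreasing in the chemical potential", {
  set.seed(3)
  pm <- rand_psam(7)
  s <- rand_seq(50)
  mus <- sort(default_mu_ladder())
  ps <- vapply(mus, function(mu) binding_probability_fast(s, pm, mu), 0)
  expect_true(all(diff(ps) >= 0))
})

test_that("occupancy over both strands is reverse-complement symmetric", {
  set.seed(5)
  for (i in 1:10) {
    pm <- rand_psam(6)
    s <- rand_seq(40)
    expect_equal(binding_probability_fast(s, pm, -13, "both"),
                 binding_probability_fast(revcomp(s), pm, -13, "both"),
                 tolerance = 1e-12)
  }
})

test_that("dbA is zero for composition-invariant occupancy and never negative", {
  p0 <- psam("Z", matrix(0, 5, 4))
  expect_equal(dba(rand_seq(30), p0, 0, n_shuffles = 20, seed = 1), 0)
  set.seed(8)
  for (i in 1:20) {
    v <- dba(rand_seq(40), rand_psam(6), runif(1, -18, 0),
             n_shuffles = 30, seed = i)
    expect_gte(v, 0)
  }
})

test_that("dbA matches an independent re-implementation of the recipe", {
  # independent path: R-level composition-preserving shuffles driven by the
  # same mt19937 stream is not available from R, so instead verify the two
  # defining properties separately: determinism under the seed, and the
  # value being occupancy minus a shuffle-mean that converges for large
  # n_shuffles to the mean over R-generated shuffles
  pm <- psam_from_consensus("T", "TTCCGGAA")
  s <- paste0(rand_seq(10), "TTCCGGAA", rand_seq(10))
  v1 <- dba(s, pm, -13, n_shuffles = 100, seed = 9)
  v2 <- dba(s, pm, -13, n_shuffles = 100, seed = 9)
  expect_identical(v1, v2)
  expect_gt(v1, 0)
  # convergence check against an R-side shuffle mean
  set.seed(77)
  ch <- strsplit(s, "")[[1]]
  bg <- mean(replicate(400, binding_probability_fast(
    paste(sample(ch), collapse = ""), pm, -13)))
  expected <- max(0, binding_probability_fast(s, pm, -13) - bg)
  v3 <- dba(s, pm, -13, n_shuffles = 400, seed = 5)
  expect_equal(v3, expected, tolerance = 0.05)
})

test_that("delta-dbA is zero on identity, antisymmetric, and detects site gain", {
  pm <- psam_from_consensus("T", "TTCC")
  set.seed(21)
  ref <- paste0(rand_seq(12), "TTGC", rand_seq(12))  # broken site
  alt <- sub("TTGC", "TTCC", ref)                    # SNV completes TTCC
  expect_identical(delta_dba(ref, ref, pm, -13, 50, seed = 2), 0)
  d1 <- delta_dba(ref, alt, pm, -13, 50, seed = 2)
  d2 <- delta_dba(alt, ref, pm, -13, 50, seed = 2)
  expect_equal(d1, -d2)
  expect_gt(d1, 0)
})
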