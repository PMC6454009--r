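#' Run the pipeline on a generated fixture
#'
#' Convenience wrapper used by the validation experiments: materializes a
#' fixture, runs the full pipeline on it, and returns the truth manifest
#' together with the parsed per-block significance tables.
#'
#' @param spec A [fixture_spec()] (or a preset name for
#'   [fixture_preset()]).
#' @param dir Working directory for the fixture and the run output.
#' @param seed Fixture seed (also used, offset, for the pipeline).
#' @param ... [pipeline_config()] overrides.
#' @return List with `truth` (data frame), `reports` (list of per-block
#'   tables with block coordinates attached) and `out_dir`.
#' @export
run_fixture_pipeline <- function(spec, dir = tempfile("fixture"), seed = 1, ...) {
  if (is.character(spec)) spec <- fixture_preset(spec, seed = seed)
  fx <- make_fixture(spec, file.path(dir, "data"))
  out <- file.path(dir, "out")
  cfg <- pipeline_config(list(genome = fx$genome, mutations = fx$mutations,
                              annotation = fx$annotation,
                              expr_patients = fx$expr_patients,
                              expr_normals = fx$expr_normals,
                              psam_dir = fx$psam_dir, out_dir = out,
                              seed = derive_seed(seed, 17L)), ...)
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
  reports <- lapply(list.files(file.path(out, "significance"),
                               pattern = "_report\\.tsv$", full.names = TRUE),
                    function(f) {
    tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    coords <- strsplit(sub("_report\\.tsv$", "", basename(f)), "_")[[1L]]
    n <- length(coords)
    attr(tab, "chrom") <- paste(coords[seq_len(n - 2L)], collapse = "_")
    attr(tab, "start") <- as.numeric(coords[[n - 1L]])
    attr(tab, "end") <- as.numeric(coords[[n]])
    tab
  })
  list(truth = fx$truth_df, reports = reports, out_dir = out, dir = dir)
}

#' Parameter-recovery experiment on implanted-effect fixtures
#'
#' Generates `n_fixtures` seeded recovery fixtures (two implanted effects
#' each: one binding-site creation, one destruction, 12 carrier patients),
#' runs the pipeline on each, and scores an implanted (TF, direction) pair
#' as recovered when the block overlapping the implanted motif reports
#' that TF significant with the matching sign.
#'
#' @param n_fixtures Number of fixtures.
#' @param seed Master seed.
#' @param n_background Background blocks per patient block.
#' @param alpha Corrected-p threshold.
#' @param background_model Background mutation model for the runs.  The
#'   default is the tumor-derived model with single-base (`k = 1`)
#'   contexts: toy cohorts observe too few distinct trinucleotide contexts
#'   to support context-conditioned placement on arbitrary short windows.
#' @param k Context length for the tumor-derived model.
#' @return List with `recovered_fraction`, and `detail` (one row per
#'   implanted effect).
#' @export
recovery_experiment <- function(n_fixtures = 20, seed = 1, n_background = 200,
                                alpha = 0.05,
                                background_model = "tumor_derived", k = 1) {
  rows <- list()
  for (i in seq_len(n_fixtures)) {
    res <- run_fixture_pipeline("recovery", seed = derive_seed(seed, 11L, i),
                                background_model = background_model,
                                n_background = n_background,
                                sig_alpha = alpha, k = k)
    for (j in seq_len(nrow(res$truth))) {
      tr <- res$truth[j, ]
      found <- FALSE
      for (tab in res$reports) {
        if (attr(tab, "chrom") != tr$chrom ||
            attr(tab, "start") > tr$motif_start ||
            attr(tab, "end") < tr$motif_end) next
        hit <- tab$tf == tr$tf & tab$significant & tab$direction == tr$direction
        if (any(hit)) found <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fixture = i, tf = tr$tf, direction = tr$direction, recovered = found,
        stringsAsFactors = FALSE)
    }
    unlink(res$dir, recursive = TRUE)
  }
  detail <- do.call(rbind, rows)
  list(recovered_fraction = mean(detail$recovered), detail = detail)
}

#' Type-I-error experiment on pure-null fixtures
#'
#' Generates `n_fixtures` pure-null fixtures (patient mutations drawn from
#' the uniform background mutation process over the block), runs the
#' pipeline with `flank = 0` (so the patient and background mutation
#' processes coincide exactly over the block) and the uniform background
#' model, and counts runs reporting zero significant TFs.
#'
#' @inheritParams recovery_experiment
#' @return List with `clean_fraction` (runs with zero significant TFs) and
#'   `n_significant` per run.
#' @export
null_experiment <- function(n_fixtures = 20, seed = 1, n_background = 200,
                            alpha = 0.05) {
  n_sig <- integer(n_fixtures)
  for (i in seq_len(n_fixtures)) {
    res <- run_fixture_pipeline("null", seed = derive_seed(seed, 13L, i),
                                background_model = "uniform",
                                n_background = n_background,
                                sig_alpha = alpha, flank = 0)
    n_sig[[i]] <- sum(vapply(res$reports, function(tab) sum(tab$significant),
                             numeric(1L)))
    unlink(res$dir, recursive = TRUE)
  }
  list(clean_fraction = mean(n_sig == 0L), n_significant = n_sig)
}

#' Background-saturation experiment on a recovery fixture
#'
#' Runs one recovery fixture, generates a full background set of `full_n`
#' blocks for its first implanted block, and evaluates the saturation
#' curve `Y(n)` over `grid` (see [background_saturation()]).
#'
#' @param seed Master seed.
#' @param full_n Full background size.
#' @param grid Background-block counts to evaluate (the full size is
#'   appended).
#' @param alpha Corrected-p threshold.
#' @param n_shuffles Shuffles per dbA evaluation.
#' @return Data frame with columns `n` and `Y`.
#' @export
saturation_experiment <- function(seed = 1, full_n = 4000,
                                  grid = c(100, 250, 500, 1000, 2000),
                                  alpha = 0.05, n_shuffles = 100) {
  dir <- tempfile("saturation")
  fx <- make_fixture(fixture_preset("recovery", seed = derive_seed(seed, 19L)),
                     file.path(dir, "data"))
  genome <- read_genome_fasta(fx$genome)
  mutations <- read_mutations(fx$mutations, genome)
  psams <- read_psam_collection(fx$psam_dir)
  regions <- promoter_regions(fx$annotation, 2000, 100, genome)
  de <- ks_differential_genes(read_expression(fx$expr_patients),
                              read_expression(fx$expr_normals))
  regions <- regions[regions$name %in% de$gene, , drop = FALSE]
  hotspots <- find_hotspots(mutations, regions)
  blocks <- build_blocks(hotspots, genome)
  blk <- blocks[[1L]]
  s <- derive_seed(seed, 23L)
  ds <- compute_block_deltas(blk, psams, n_shuffles = n_shuffles, seed = s)
  bg <- generate_background_set(blk, regions, genome, model = "uniform",
                                n_blocks = full_n, seed = s)
  bgd <- compute_background_deltas(bg, psams, n_shuffles = n_shuffles, seed = s)
  grid <- sort(unique(c(grid[grid <= full_n], full_n)))
  sat <- background_saturation(ds, bgd, grid, alpha = alpha)
  unlink(dir, recursive = TRUE)
  sat
}
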