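#' Pipeline configuration
#'
#' Builds and validates the configuration for an end-to-end run.  Accepts
#' a YAML file path or a named list; `...` overrides individual entries.
#' Required path entries: `genome`, `mutations`, `annotation`,
#' `expr_patients`, `expr_normals` (or `de_gene_list` instead of the two
#' expression tables), `psam_dir`, `out_dir`.  Optional: `signature_file`.
#'
#' @param config YAML path or named list.
#' @param ... Individual overrides (e.g. `seed = 7`, `n_background = 500`).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    genome = NULL, mutations = NULL, annotation = NULL,
    expr_patients = NULL, expr_normals = NULL, de_gene_list = NULL,
    psam_dir = NULL, signature_file = NULL, out_dir = NULL,
    upstream = 2000, downstream = 100,
    de_alpha = 0.05, de_correction = "none",
    max_gap = 30, min_mutations = 2, min_patients = 2, flank = 25,
    mus = default_mu_ladder(), n_shuffles = 100, strand = "both",
    background_model = "tumor_derived", n_background = 2000, k = 3,
    sig_alpha = 0.001, seed = 1,
    n_workers = 1, scheduler = "local")
  cfg <- modifyList(defaults, config)
  cfg <- modifyList(cfg, list(...))
  cfg$mus <- as.numeric(unlist(cfg$mus))
  for (p in c("genome", "mutations", "annotation", "psam_dir", "out_dir")) {
    if (is.null(cfg[[p]])) stop("pipeline config is missing required path: ", p)
  }
  using_list <- !is.null(cfg$de_gene_list)
  if (!using_list && (is.null(cfg$expr_patients) || is.null(cfg$expr_normals)))
    stop("pipeline config needs either expression tables or a de_gene_list")
  if (using_list && !is.null(cfg$expr_patients))
    stop("expression tables and de_gene_list are mutually exclusive")
  for (p in c("genome", "mutations", "annotation", "expr_patients",
              "expr_normals", "de_gene_list", "psam_dir", "signature_file")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("pipeline config path does not exist: ", p, " = ", cfg[[p]])
  }
  stopifnot(cfg$upstream >= 0, cfg$downstream >= 0,
            cfg$de_alpha > 0, cfg$de_alpha <= 1,
            cfg$de_correction %in% c("none", "bonferroni"),
            cfg$max_gap >= 1, cfg$min_mutations >= 1, cfg$min_patients >= 1,
            cfg$flank >= 0, length(cfg$mus) >= 1, cfg$n_shuffles >= 1,
            cfg$strand %in% c("both", "forward"),
            cfg$background_model %in% c("uniform", "signature", "tumor_derived"),
            cfg$n_background >= 1, cfg$k %in% c(1, 3),
            cfg$sig_alpha > 0, cfg$sig_alpha <= 1,
            cfg$n_workers >= 1, cfg$scheduler %in% c("local", "slurm"))
  if (cfg$background_model == "signature" && is.null(cfg$signature_file))
    stop("background_model = 'signature' requires signature_file")
  structure(cfg, class = "pipeline_config")
}

log_line <- function(out_dir, ...) {
  msg <- paste0(...)
  message(msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE, sep = "")
}

#' Run tasks in parallel with deterministic results
#'
#' Results are identical regardless of `n_workers` or scheduler: each task
#' must derive its own randomness from a per-task seed, and results are
#' collected in task order.  Local mode uses a fork-based worker pool;
#' `scheduler = "slurm"` writes a job-array script, submits it with
#' `sbatch --wait`, and collects per-task result files.
#'
#' @param tasks List of task descriptors.
#' @param fn Function applied to each task.
#' @param n_workers Worker count (1 = serial).
#' @param scheduler `"local"` or `"slurm"`.
#' @param work_dir Scratch directory for the SLURM mode.
#' @return List of results in task order.
#' @export
parallel_map <- function(tasks, fn, n_workers = 1, scheduler = c("local", "slurm"),
                         work_dir = tempfile("parallel_map")) {
  scheduler <- match.arg(scheduler)
  if (length(tasks) == 0L) return(list())
  if (scheduler == "slurm") return(slurm_map(tasks, fn, n_workers, work_dir))
  res <- if (n_workers == 1L) lapply(tasks, fn)
  else parallel::mclapply(tasks, fn, mc.cores = n_workers, mc.preschedule = TRUE)
  failed <- vapply(res, inherits, logical(1L), "try-error")
  if (any(failed))
    stop("parallel task(s) failed: ", paste(which(failed), collapse = ", "),
         "; first error: ", attr(res[[which(failed)[1L]]], "condition")$message)
  res
}

slurm_map <- function(tasks, fn, n_workers, work_dir) {
  if (Sys.which("sbatch") == "")
    stop("scheduler = 'slurm' requested but sbatch is not on PATH")
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(tasks = tasks, fn = fn), file.path(work_dir, "tasks.rds"))
  script <- file.path(work_dir, "job_array.sh")
  writeLines(c(
    "#!/bin/bash",
    paste0("#SBATCH --array=1-", length(tasks)),
    "#SBATCH --cpus-per-task=1",
    paste0("Rscript -e 'x <- readRDS(\"", file.path(work_dir, "tasks.rds"),
           "\"); i <- as.integer(Sys.getenv(\"SLURM_ARRAY_TASK_ID\")); ",
           "saveRDS(x$fn(x$tasks[[i]]), file.path(\"", work_dir,
           "\", sprintf(\"result_%05d.rds\", i)))'")), script)
  status <- system2("sbatch", c("--wait", script))
  if (status != 0L) stop("sbatch submission failed with status ", status)
  lapply(seq_along(tasks), function(i) {
    f <- file.path(work_dir, sprintf("result_%05d.rds", i))
    if (!file.exists(f)) stop("SLURM task ", i, " produced no result file")
    readRDS(f)
  })
}

#' Run the whole pipeline
#'
#' Stages run in order: differential expression (or external gene list)
#' -> hotspot detection and block building -> per-block delta-dbA ->
#' background generation and scoring -> significance reports.  Each stage
#' writes its artifact under `out_dir` and is skipped on re-run when the
#' artifact already exists, so interrupted runs resume.  A
#' `run_manifest.json` records package version and all parameters.
#'
#' Per-block scoring (the expensive part) is one parallel task per block,
#' seeded from `(seed, block index)`, so results are identical for any
#' worker count.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  genome <- read_genome_fasta(cfg$genome)
  mutations <- read_mutations(cfg$mutations, genome)
  psams <- read_psam_collection(cfg$psam_dir)

  # stage 1: differential expression
  de_file <- file.path(out, "de_genes.txt")
  if (file.exists(de_file)) {
    log_line(out, "[de] artifact exists, skipping")
    de_genes <- read_gene_list(de_file)
  } else if (!is.null(cfg$de_gene_list)) {
    de_genes <- read_gene_list(cfg$de_gene_list)
    write_gene_list(de_genes, de_file)
    log_line(out, "[de] using external gene list: ", length(de_genes), " gene(s)")
  } else {
    expr_p <- read_expression(cfg$expr_patients)
    expr_n <- read_expression(cfg$expr_normals)
    de <- ks_differential_genes(expr_p, expr_n, alpha = cfg$de_alpha,
                                correction = cfg$de_correction, keep_all = TRUE)
    write.table(de, file.path(out, "de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    de_genes <- de$gene[de$selected]
    write_gene_list(de_genes, de_file)
    log_line(out, "[de] ", length(de_genes), " differentially expressed gene(s)")
  }
  if (length(de_genes) == 0L) stop("no differentially expressed genes; nothing to scan")

  # stage 2: hotspots and blocks
  regions <- promoter_regions(cfg$annotation, cfg$upstream, cfg$downstream, genome)
  regions <- regions[regions$name %in% de_genes, , drop = FALSE]
  if (nrow(regions) == 0L) stop("no promoter regions for the DE genes")
  hotspots <- find_hotspots(mutations, regions, max_gap = cfg$max_gap,
                            min_mutations = cfg$min_mutations,
                            min_patients = cfg$min_patients, flank = cfg$flank)
  blocks <- build_blocks(hotspots, genome)
  bed_file <- file.path(out, "hotspots.bed")
  if (file.exists(bed_file)) {
    log_line(out, "[mussd] artifact exists, skipping")
  } else {
    write_hotspots_bed(hotspots, bed_file)
    block_dir <- file.path(out, "blocks")
    for (b in blocks) write_block_fasta(b, block_dir)
    log_line(out, "[mussd] ", length(hotspots), " hotspot(s) / block(s)")
  }
  if (length(blocks) == 0L) {
    log_line(out, "[mussd] no hotspots found; writing empty summary")
    write_manifest(cfg, out, 0L)
    return(invisible(out))
  }

  # stages 3-5: per-block scoring against the background model
  signature <- if (!is.null(cfg$signature_file)) read_signature(cfg$signature_file)
  dir.create(file.path(out, "deltas"), showWarnings = FALSE)
  dir.create(file.path(out, "background"), showWarnings = FALSE)
  dir.create(file.path(out, "significance"), showWarnings = FALSE)
  tasks <- seq_along(blocks)
  done <- vapply(tasks, function(i) {
    file.exists(file.path(out, "significance",
                          paste0(block_id(blocks[[i]]), "_report.tsv")))
  }, logical(1L))
  if (all(done)) {
    log_line(out, "[score] all ", length(blocks), " block report(s) exist, skipping")
  } else {
    score_one <- function(i) {
      blk <- blocks[[i]]
      id <- block_id(blk)
      task_seed <- derive_seed(cfg$seed, i)
      ds <- compute_block_deltas(blk, psams, mus = cfg$mus,
                                 n_shuffles = cfg$n_shuffles,
                                 seed = task_seed, strand = cfg$strand)
      write_delta_set(ds, file.path(out, "deltas", paste0(id, ".tsv")))
      bg <- generate_background_set(blk, regions, genome,
                                    model = cfg$background_model,
                                    n_blocks = cfg$n_background,
                                    seed = task_seed, signature = signature,
                                    mutations = mutations, k = cfg$k)
      stopifnot(check_background_set(bg, blk) == 0L)
      bgd <- compute_background_deltas(bg, psams, mus = cfg$mus,
                                       n_shuffles = cfg$n_shuffles,
                                       seed = task_seed, strand = cfg$strand)
      bg_df <- data.frame(block_index = bgd$block_index, bgd$deltas,
                          check.names = FALSE)
      write.table(bg_df, file.path(out, "background", paste0(id, "_deltas.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rep <- summarize_block(ds, bgd$deltas, alpha = cfg$sig_alpha)
      write_report(rep, file.path(out, "significance", paste0(id, "_report.tsv")),
                   file.path(out, "significance", paste0(id, "_effects.tsv")))
      list(id = id, n_significant = length(rep$significant_tfs),
           significant = rep$significant_tfs)
    }
    res <- parallel_map(tasks[!done], score_one, n_workers = cfg$n_workers,
                        scheduler = cfg$scheduler)
    for (r in res)
      log_line(out, "[score] block ", r$id, ": ", r$n_significant,
               " significant TF(s)")
  }
  write_manifest(cfg, out, length(blocks))
  invisible(out)
}

#' Background-saturation curve from a completed pipeline run
#'
#' Reads one block's delta and background artifacts back from a completed
#' output directory and evaluates [background_saturation()] on them.
#'
#' @param config A [pipeline_config()] whose `out_dir` holds a completed run.
#' @param block Block id (default: first block found).
#' @param grid Background-block counts to evaluate (clipped to the stored
#'   background size; the full size is always appended).
#' @return Data frame with columns `n` and `Y`.
#' @export
pipeline_saturation <- function(config, block = NULL,
                                grid = c(100, 250, 500, 1000, 2000)) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out <- cfg$out_dir
  delta_files <- sort(list.files(file.path(out, "deltas"), full.names = TRUE))
  if (length(delta_files) == 0L) stop("no delta artifacts under ", out)
  id <- block %||% sub("\\.tsv$", "", basename(delta_files[[1L]]))
  dd <- read.table(file.path(out, "deltas", paste0(id, ".tsv")), header = TRUE,
                   sep = "\t", check.names = FALSE)
  deltas <- t(as.matrix(dd[, -1L, drop = FALSE]))
  colnames(deltas) <- dd$tf
  ds <- structure(list(block_id = id, tf_ids = dd$tf,
                       patient_ids = rownames(deltas),
                       patient_deltas = deltas), class = "delta_set")
  bd <- read.table(file.path(out, "background", paste0(id, "_deltas.tsv")),
                   header = TRUE, sep = "\t", check.names = FALSE)
  background <- list(deltas = as.matrix(bd[, -1L, drop = FALSE]),
                     block_index = bd$block_index)
  full_n <- max(background$block_index)
  grid <- sort(unique(c(grid[grid <= full_n], full_n)))
  background_saturation(ds, background, grid, alpha = cfg$sig_alpha)
}

write_manifest <- function(cfg, out, n_blocks) {
  manifest <- list(
    package = "regmutscan",
    version = as.character(utils::packageVersion("regmutscan")),
    n_blocks = n_blocks,
    parameters = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(NULL)
}
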