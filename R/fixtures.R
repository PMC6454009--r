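#' Specification of a synthetic cohort fixture
#'
#' Describes a fully synthetic, seeded dataset: a random genome, gene
#' annotation, patient/normal RPKM tables, somatic mutations with
#' implanted ground-truth TF binding effects, and matching consensus-built
#' PSAMs.  Implanted effects either destroy a consensus site written into
#' a gene's promoter (carrier SNVs break consensus bases) or create one
#' (the promoter carries the consensus with one mismatch and carrier SNVs
#' complete it, emulating recurrent hotspot mutations).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Number of genes (TSSs evenly spaced with jitter).
#' @param n_patients,n_normals Cohort sizes.
#' @param effects List of implanted effects; each a list with fields
#'   `gene` (index), `tf`, `consensus`, `effect` (`"create"`/`"destroy"`),
#'   `n_carriers`.
#' @param n_decoy_psams Unrelated random-consensus PSAMs added to the
#'   collection.
#' @param background_rate Background somatic SNV rate per promoter bp per
#'   patient.
#' @param de_shift Multiplicative RPKM shift for affected genes in
#'   patients.
#' @param upstream,downstream Promoter window extents used when placing
#'   effects.
#' @param null_cluster If `TRUE`, implant a pure-null mutation cluster:
#'   every patient receives one uniformly placed, uniformly substituted
#'   SNV in a `null_window`-bp window of a DE gene's promoter, so hotspot
#'   detection fires but binding effects are null (the patient mutation
#'   process equals the uniform background mutation process).
#' @param null_window Width (bp) of the pure-null cluster window.
#' @param seed Integer seed; the fixture is byte-identical given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chromosomes = 1, chrom_length = 30000, n_genes = 8,
                         n_patients = 12, n_normals = 8, effects = list(),
                         n_decoy_psams = 3, background_rate = 2e-5,
                         de_shift = 4, upstream = 2000, downstream = 100,
                         null_cluster = FALSE, null_window = 80, seed = 1) {
  for (e in effects) {
    stopifnot(e$effect %in% c("create", "destroy"),
              nchar(e$consensus) >= 4, e$gene >= 1, e$gene <= n_genes,
              e$n_carriers >= 1, e$n_carriers <= n_patients)
  }
  if (length(effects) > 1L) {
    genes <- vapply(effects, `[[`, numeric(1L), "gene")
    if (anyDuplicated(genes))
      stop("implanted effects collide: two effects target the same gene promoter")
  }
  structure(as.list(environment()), class = "fixture_spec")
}

#' Preset fixture specifications
#'
#' * `demo` - one destroy effect, light background mutations.
#' * `recovery` - one create and one destroy effect with 12 carriers
#'   each, the configuration used for parameter-recovery validation.
#' * `null` - no implanted effects; a clustered pure-null mutation block
#'   for type-I-error checks.
#'
#' @param preset One of `"demo"`, `"recovery"`, `"null"`.
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
fixture_preset <- function(preset = c("demo", "recovery", "null"), seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    demo = fixture_spec(
      effects = list(list(gene = 1, tf = "TF_DEST", consensus = "TGACGTCA",
                          effect = "destroy", n_carriers = 12)),
      background_rate = 2e-5, seed = seed),
    recovery = fixture_spec(
      effects = list(
        list(gene = 1, tf = "TF_CREA", consensus = "GGAAGTGC",
             effect = "create", n_carriers = 12),
        list(gene = 3, tf = "TF_DEST", consensus = "TGACGTCA",
             effect = "destroy", n_carriers = 12)),
      background_rate = 1e-5, seed = seed),
    null = fixture_spec(effects = list(), null_cluster = TRUE,
                        background_rate = 0, n_decoy_psams = 30, seed = seed))
}

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Materialize a synthetic fixture on disk
#'
#' Writes `genome.fa`, `annotation.bed` (BED6, one TSS per gene),
#' `mutations.tsv`, `expr_patients.tsv`, `expr_normals.tsv`, a `psams/`
#' directory, and `truth.tsv` (the ground-truth manifest listing implanted
#' (gene, TF, direction) pairs and their SNV positions) into `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created).
#' @return Invisibly, a list with the file paths and the `truth` data
#'   frame.
#' @export
make_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  seqs <- setNames(vapply(chroms, function(ch) rand_dna(spec$chrom_length),
                          character(1L)), chroms)

  # evenly spaced TSSs with jitter, margins large enough that no promoter
  # window is clipped
  margin <- spec$upstream + spec$downstream + 200
  per_chrom <- ceiling(spec$n_genes / spec$n_chromosomes)
  ann <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    idx <- seq_len(per_chrom) + (ci - 1L) * per_chrom
    idx <- idx[idx <= spec$n_genes]
    if (length(idx) == 0L) return(NULL)
    span <- spec$chrom_length - 2 * margin
    tss <- margin + round(seq(0, span, length.out = max(2L, length(idx)))[seq_along(idx)]) +
      sample(-50:50, length(idx), replace = TRUE)
    data.frame(chrom = chroms[[ci]], tss = tss,
               gene = paste0("gene", idx),
               strand = rep(c("+", "-"), length.out = length(idx)),
               stringsAsFactors = FALSE)
  }))

  patients <- sprintf("P%02d", seq_len(spec$n_patients))
  normals <- sprintf("N%02d", seq_len(spec$n_normals))

  # PSAM collection: implanted TFs plus unrelated decoys
  psams <- list()
  for (e in spec$effects)
    psams[[e$tf]] <- psam_from_consensus(e$tf, e$consensus)
  for (d in seq_len(spec$n_decoy_psams)) {
    nm <- paste0("TF_DECOY", d)
    psams[[nm]] <- psam_from_consensus(nm, rand_dna(8L))
  }

  # implant motifs into promoters and derive carrier SNVs
  mut <- list()
  truth <- list()
  affected_genes <- character(0L)
  for (e in spec$effects) {
    g <- ann[ann$gene == paste0("gene", e$gene), ]
    L <- nchar(e$consensus)
    m0 <- if (g$strand == "+") g$tss - 300L else g$tss + 300L - L + 1L  # 0-based
    cons <- strsplit(e$consensus, "")[[1L]]
    planted <- cons
    if (e$effect == "create") {
      # one mismatch mid-motif; every carrier's SNV restores the consensus
      mm <- ceiling(L / 2)
      ref_base <- sample(setdiff(DNA_BASES, cons[[mm]]), 1L)
      planted[[mm]] <- ref_base
    }
    substr(seqs[[g$chrom]], m0 + 1L, m0 + L) <- paste(planted, collapse = "")
    carriers <- patients[seq_len(e$n_carriers)]
    pos1 <- integer(0L)
    for (p in carriers) {
      if (e$effect == "create") {
        j <- ceiling(L / 2)
        alt <- cons[[j]]
      } else {
        j <- sample.int(L, 1L)
        alt <- sample(setdiff(DNA_BASES, planted[[j]]), 1L)
      }
      pos <- m0 + j  # 1-based genomic position of motif offset j
      mut[[length(mut) + 1L]] <- data.frame(
        chrom = g$chrom, pos = pos, ref = planted[[j]], alt = alt,
        patient = p, stringsAsFactors = FALSE)
      pos1 <- c(pos1, pos)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      gene = g$gene, tf = e$tf, effect = e$effect,
      direction = if (e$effect == "create") "positive" else "negative",
      n_carriers = e$n_carriers, chrom = g$chrom,
      motif_start = m0, motif_end = m0 + L,
      positions = paste(sort(unique(pos1)), collapse = ","),
      stringsAsFactors = FALSE)
    affected_genes <- c(affected_genes, g$gene)
  }

  # pure-null clustered mutations: uniform positions, uniform substitutions
  if (isTRUE(spec$null_cluster)) {
    g <- ann[1L, ]
    c0 <- if (g$strand == "+") g$tss - 300L else g$tss + 300L
    win <- spec$null_window
    for (p in patients) {
      pos <- c0 - win %/% 2L + sample.int(win, 1L)  # 1-based
      ref <- substr(seqs[[g$chrom]], pos, pos)
      alt <- sample(setdiff(DNA_BASES, ref), 1L)
      mut[[length(mut) + 1L]] <- data.frame(
        chrom = g$chrom, pos = pos, ref = ref, alt = alt, patient = p,
        stringsAsFactors = FALSE)
    }
    affected_genes <- c(affected_genes, g$gene)
  }

  # background somatic SNVs sprinkled over the promoter windows
  if (spec$background_rate > 0) {
    prom <- data.frame(
      chrom = ann$chrom,
      start = ifelse(ann$strand == "+", ann$tss - spec$upstream,
                     ann$tss - spec$downstream),
      end = ifelse(ann$strand == "+", ann$tss + spec$downstream + 1,
                   ann$tss + spec$upstream + 1))
    widths <- prom$end - prom$start
    total_bp <- sum(widths)
    cum <- cumsum(widths)
    for (p in patients) {
      n_bg <- rpois(1L, spec$background_rate * total_bp)
      if (n_bg == 0L) next
      u <- sample.int(total_bp, n_bg, replace = TRUE)
      ri <- findInterval(u - 1, cum) + 1L
      pos <- prom$start[ri] + (u - c(0, cum)[ri])  # 1-based
      for (i in seq_len(n_bg)) {
        ref <- substr(seqs[[prom$chrom[ri[i]]]], pos[i], pos[i])
        mut[[length(mut) + 1L]] <- data.frame(
          chrom = prom$chrom[ri[i]], pos = pos[i], ref = ref,
          alt = sample(setdiff(DNA_BASES, ref), 1L), patient = p,
          stringsAsFactors = FALSE)
      }
    }
  }

  mutations <- do.call(rbind, mut)
  if (is.null(mutations))
    mutations <- data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            patient = character(), stringsAsFactors = FALSE)
  # one call per (patient, position): drop colliding duplicates
  mutations <- mutations[!duplicated(mutations[, c("patient", "chrom", "pos")]), ]
  mutations <- mutations[order(mutations$chrom, mutations$pos, mutations$patient), ]
  rownames(mutations) <- NULL

  # RPKM tables: lognormal baselines; affected genes shifted in patients
  base_rpkm <- exp(rnorm(spec$n_genes, log(10), 0.5))
  names(base_rpkm) <- paste0("gene", seq_len(spec$n_genes))
  noise <- function(n) exp(rnorm(n, 0, 0.2))
  pat_vals <- t(vapply(names(base_rpkm), function(g) {
    shift <- if (g %in% affected_genes) spec$de_shift else 1
    base_rpkm[[g]] * shift * noise(spec$n_patients)
  }, numeric(spec$n_patients)))
  norm_vals <- t(vapply(names(base_rpkm), function(g)
    base_rpkm[[g]] * noise(spec$n_normals), numeric(spec$n_normals)))
  expr_p <- expression_table(names(base_rpkm), patients, pat_vals)
  expr_n <- expression_table(names(base_rpkm), normals, norm_vals)

  # write everything
  paths <- list(genome = file.path(dir, "genome.fa"),
                annotation = file.path(dir, "annotation.bed"),
                mutations = file.path(dir, "mutations.tsv"),
                expr_patients = file.path(dir, "expr_patients.tsv"),
                expr_normals = file.path(dir, "expr_normals.tsv"),
                psam_dir = file.path(dir, "psams"),
                truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), paths$genome)
  bed <- data.frame(ann$chrom, ann$tss, ann$tss + 1L, ann$gene, 0L, ann$strand)
  write.table(bed, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_mutations(mutations, paths$mutations)
  write_expression(expr_p, paths$expr_patients)
  write_expression(expr_n, paths$expr_normals)
  dir.create(paths$psam_dir, showWarnings = FALSE)
  for (nm in names(psams))
    write_psam(psams[[nm]], file.path(paths$psam_dir, paste0(nm, ".psam")))
  truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene = character(), tf = character(), effect = character(),
               direction = character(), n_carriers = integer(),
               chrom = character(), motif_start = integer(),
               motif_end = integer(), positions = character(),
               stringsAsFactors = FALSE)
  write.table(truth_df, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(paths, list(truth_df = truth_df, spec = spec)))
}
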