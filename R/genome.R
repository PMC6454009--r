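#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on read (soft-masked lowercase bases are kept,
#' as uppercase) and held in memory as plain character strings keyed by the
#' first word of each FASTA header.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `genome`: one uppercase DNA
#'   string per chromosome, over the alphabet `A`, `C`, `G`, `T`, `N`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, n = 50L)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("FASTA format error in ", path, ": file is empty")
  if (!startsWith(lines[[1L]], ">"))
    stop("FASTA format error in ", path, " at line 1: expected a '>' header, got: ",
         substr(lines[[1L]], 1L, 40L))
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- vapply(strsplit(names(dss), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names in ", path)
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in ", path)
  structure(seqs, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", length(x), " chromosome(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

genome_base <- function(genome, chrom, pos) {
  # pos is 1-based here (mutation coordinates)
  substr(genome[[chrom]], pos, pos)
}

#' Extract the forward-strand sequence of a region
#'
#' Coordinates are 0-based half-open; the returned sequence is always the
#' forward strand regardless of the region's strand annotation (strand is
#' only a TSS convention).
#'
#' @param genome A [read_genome_fasta()] object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return A DNA string of length `end - start`.
#' @export
extract_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop("region ", chrom, ":", start, "-", end,
         " out of bounds for chromosome of length ", len)
  substr(genome[[chrom]], start + 1L, end)
}

#' Read somatic single-nucleotide mutations
#'
#' Accepts a 5-column TSV (header `chrom pos ref alt patient`, positions
#' 1-based) or a VCF 4.x file.  Only single-nucleotide substitutions are
#' retained; indels and multi-allelic records are skipped with a logged
#' count.  Every retained mutation's ref allele is checked against the
#' genome; the run aborts when the mismatch rate exceeds
#' `max_mismatch_rate` (a genome-build mismatch symptom).
#'
#' @param path Input file.
#' @param genome Genome used for ref-allele validation.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param patient Patient id to assign to every record of a VCF that has no
#'   sample columns (required in that case).
#' @param max_mismatch_rate Abort threshold for the ref-mismatch fraction.
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `patient`.
#' @export
read_mutations <- function(path, genome, format = c("auto", "tsv", "vcf"),
                           patient = NULL, max_mismatch_rate = 0.01) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  raw <- if (format == "vcf") read_mutations_vcf(path, patient) else read_mutations_tsv(path)

  snv <- nchar(raw$ref) == 1L & nchar(raw$alt) == 1L &
    raw$ref %in% DNA_BASES & raw$alt %in% DNA_BASES & raw$ref != raw$alt
  n_skipped <- sum(!snv)
  if (n_skipped > 0L)
    message("read_mutations: skipped ", n_skipped,
            " non-SNV (indel/multi-allelic/ambiguous) record(s)")
  mut <- raw[snv, , drop = FALSE]
  if (nrow(mut) == 0L) return(mut)

  known <- mut$chrom %in% names(genome)
  if (any(!known)) {
    warning("dropping ", sum(!known), " mutation(s) on chromosomes absent from the genome")
    mut <- mut[known, , drop = FALSE]
  }
  gbase <- mapply(genome_base, chrom = mut$chrom, pos = mut$pos,
                  MoreArgs = list(genome = genome), USE.NAMES = FALSE)
  mism <- gbase != mut$ref
  if (mean(mism) > max_mismatch_rate)
    stop(sprintf(paste0("ref allele mismatch rate %.1f%% exceeds %.1f%%: the mutation ",
                        "coordinates likely use a different genome build"),
                 100 * mean(mism), 100 * max_mismatch_rate))
  if (any(mism)) {
    warning("dropping ", sum(mism), " mutation(s) whose ref allele disagrees with the genome")
    mut <- mut[!mism, , drop = FALSE]
  }
  rownames(mut) <- NULL
  mut
}

read_mutations_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "patient")
  if (!all(need %in% names(df)))
    stop("mutation TSV must have header columns: ", paste(need, collapse = " "))
  data.frame(chrom = df$chrom, pos = as.integer(df$pos),
             ref = toupper(df$ref), alt = toupper(df$alt),
             patient = df$patient, stringsAsFactors = FALSE)
}

read_mutations_vcf <- function(path, patient = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  base <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
                     stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) <= 1L) {
    if (is.null(patient))
      stop("VCF ", path, " has no sample columns; supply `patient` explicitly")
    base$patient <- patient
    return(base)
  }
  samples <- colnames(gt)[-1L]
  gtm <- vcfR::extract.gt(v, element = "GT")
  carried <- !is.na(gtm) & !gtm %in% c("0/0", "0|0", ".", "./.", ".|.")
  out <- do.call(rbind, lapply(seq_along(samples), function(k) {
    rows <- which(carried[, k])
    if (length(rows) == 0L) return(NULL)
    cbind(base[rows, , drop = FALSE],
          patient = rep(samples[[k]], length(rows)))
  }))
  if (is.null(out))
    out <- cbind(base[0L, , drop = FALSE], patient = character(0L))
  out
}

#' Write mutations to the 5-column TSV interchange format
#' @param mutations Mutation data frame as returned by [read_mutations()].
#' @param path Output file.
#' @export
write_mutations <- function(mutations, path) {
  write.table(mutations[, c("chrom", "pos", "ref", "alt", "patient")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Promoter regions around gene TSSs
#'
#' Reads a BED6 or GTF annotation and returns one promoter window per gene,
#' `[tss - upstream, tss + downstream]` on the gene's strand, as 0-based
#' half-open intervals.  For genes with multiple transcripts the outermost
#' (5'-most) TSS is used, so the DE-gene-to-region map stays one-to-one.
#'
#' @param annotation_path BED6 (TSS = start on `+`, end-1 on `-`) or GTF
#'   (TSS = transcript 5' end).
#' @param upstream,downstream Non-negative window extents in bp.
#' @param genome Optional genome; when given, regions are clipped to
#'   chromosome bounds and regions on unknown chromosomes are skipped with
#'   a warning.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name` (gene id), `strand`.
#' @export
promoter_regions <- function(annotation_path, upstream = 2000, downstream = 100,
                             genome = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  fmt <- if (grepl("\\.(gtf|gff)(\\.gz)?$", annotation_path, ignore.case = TRUE))
    "gtf" else "bed"
  gr <- rtracklayer::import(annotation_path, format = fmt)
  if (fmt == "gtf") {
    md <- as.data.frame(GenomicRanges::mcols(gr))
    keep <- if ("type" %in% names(md)) as.character(md$type) %in%
      c("transcript", "mRNA", "gene") else rep(TRUE, length(gr))
    gr <- gr[keep]
    md <- md[keep, , drop = FALSE]
    gene <- md$gene_id %||% md$gene_name
    if (is.null(gene)) stop("GTF lacks gene_id/gene_name attributes")
  } else {
    gene <- GenomicRanges::mcols(gr)$name
    if (is.null(gene)) stop("BED annotation needs a name column (BED6)")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    warning("features without strand treated as '+'")
    strand[strand == "*"] <- "+"
  }
  # 0-based TSS per feature
  tss <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   tss = tss, name = as.character(gene), strand = strand,
                   stringsAsFactors = FALSE)
  # outermost (5'-most) TSS per gene
  df <- do.call(rbind, lapply(split(df, df$name), function(d) {
    i <- if (d$strand[[1L]] == "+") which.min(d$tss) else which.max(d$tss)
    d[i, , drop = FALSE]
  }))
  start <- ifelse(df$strand == "+", df$tss - upstream, df$tss - downstream)
  end <- ifelse(df$strand == "+", df$tss + downstream + 1, df$tss + upstream + 1)
  out <- data.frame(chrom = df$chrom, start = as.numeric(start),
                    end = as.numeric(end), name = df$name, strand = df$strand,
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    known <- out$chrom %in% names(genome)
    if (any(!known)) {
      warning("skipping ", sum(!known), " gene(s) on chromosomes absent from the genome: ",
              paste(unique(out$chrom[!known]), collapse = ", "))
      out <- out[known, , drop = FALSE]
    }
    lens <- nchar(genome)[out$chrom]
    out$start <- pmax(0, out$start)
    out$end <- pmin(as.numeric(lens), out$end)
  } else {
    out$start <- pmax(0, out$start)
  }
  out <- out[out$start < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge overlapping regions (used before hotspot clustering so one locus is
# never reported under two gene names).  Names of merged regions are joined
# with ",".
merge_regions <- function(regions) {
  if (nrow(regions) == 0L) return(regions)
  ir <- split(IRanges::IRanges(start = regions$start + 1L, end = regions$end),
              regions$chrom)
  out <- lapply(names(ir), function(ch) {
    red <- IRanges::reduce(ir[[ch]])
    hits <- IRanges::findOverlaps(ir[[ch]], red)
    nm <- vapply(seq_along(red), function(i) {
      idx <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
      paste(unique(regions$name[regions$chrom == ch][idx]), collapse = ",")
    }, character(1L))
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), name = nm, strand = "+",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
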