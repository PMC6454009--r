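#' Mutation hotspot detection by spatial and cross-sample clustering
#'
#' Within each (merged) promoter region, mutations sorted by position are
#' single-linkage clustered with inter-mutation gap <= `max_gap`.  A
#' cluster becomes a hotspot when it contains at least `min_mutations`
#' mutations from at least `min_patients` distinct patients — recurrence
#' across patients is required, a pile-up from a single sample is not a
#' hotspot.  The hotspot region is the cluster span extended by `flank`
#' bp on each side (clipped to the promoter region), so downstream motif
#' scans have sequence context across cluster edges.
#'
#' @param mutations Mutation data frame (see [read_mutations()]); only
#'   mutations inside `regions` are considered.
#' @param regions Promoter regions from [promoter_regions()]; overlapping
#'   regions are merged before clustering so one locus is never reported
#'   under two gene names.
#' @param max_gap Maximum gap (bp) between consecutive cluster members.
#' @param min_mutations Minimum mutations per hotspot.
#' @param min_patients Minimum distinct patients per hotspot.
#' @param flank Context added on each side of the cluster span (bp).
#' @return A list of `hotspot` objects sorted by `n_patients` decreasing
#'   (ties: by position).  Each has `region` (chrom/start/end 0-based
#'   half-open), `mutations`, `n_patients`, `nearest_gene`.
#' @export
find_hotspots <- function(mutations, regions, max_gap = 30, min_mutations = 2,
                          min_patients = 2, flank = 25) {
  stopifnot(max_gap >= 1)
  merged <- merge_regions(regions)
  hot <- list()
  for (r in seq_len(nrow(merged))) {
    reg <- merged[r, ]
    inside <- mutations$chrom == reg$chrom &
      mutations$pos - 1L >= reg$start & mutations$pos - 1L < reg$end
    mu <- mutations[inside, , drop = FALSE]
    if (nrow(mu) == 0L) next
    mu <- mu[order(mu$pos, mu$patient, mu$alt), , drop = FALSE]
    gap_break <- c(FALSE, diff(mu$pos) > max_gap)
    cl <- cumsum(gap_break)
    for (k in unique(cl)) {
      cm <- mu[cl == k, , drop = FALSE]
      np <- length(unique(cm$patient))
      if (nrow(cm) < min_mutations || np < min_patients) next
      start <- max(reg$start, min(cm$pos) - 1L - flank)
      end <- min(reg$end, max(cm$pos) + flank)
      hot[[length(hot) + 1L]] <- structure(
        list(region = data.frame(chrom = reg$chrom, start = start, end = end,
                                 stringsAsFactors = FALSE),
             mutations = cm, n_patients = np, nearest_gene = reg$name),
        class = "hotspot")
    }
  }
  ord <- order(-vapply(hot, `[[`, numeric(1L), "n_patients"),
               vapply(hot, function(h) h$region$chrom, character(1L)),
               vapply(hot, function(h) h$region$start, numeric(1L)))
  hot[ord]
}

#' @export
print.hotspot <- function(x, ...) {
  cat("<hotspot> ", x$region$chrom, ":", x$region$start, "-", x$region$end,
      " (", x$nearest_gene, "): ", nrow(x$mutations), " mutations, ",
      x$n_patients, " patients\n", sep = "")
  invisible(x)
}

#' Build patient-specific mutation blocks from hotspots
#'
#' For each hotspot, takes the reference sequence of the hotspot region
#' from the genome and, for every patient with at least one mutation in
#' it, an alternate sequence carrying all of that patient's mutations in
#' the region.  Alternate sequences have the same length as the reference
#' (SNVs only) and differ from it exactly at the patient's mutated
#' offsets.
#'
#' @param hotspots List of hotspots from [find_hotspots()].
#' @param genome Genome object.
#' @return List of `mutation_block` objects with fields `hotspot`,
#'   `ref_seq` and named list `alt_seqs` (patient -> DNA string).
#' @export
build_blocks <- function(hotspots, genome) {
  lapply(hotspots, function(h) {
    ref <- extract_sequence(genome, h$region$chrom, h$region$start, h$region$end)
    alt_seqs <- lapply(split(h$mutations, h$mutations$patient), function(pm) {
      off <- pm$pos - 1L - h$region$start  # 0-based offset in block
      if (anyDuplicated(off)) {
        dup <- off[duplicated(off)]
        bad <- pm[off %in% dup, , drop = FALSE]
        if (any(tapply(bad$alt, bad$pos, function(a) length(unique(a))) > 1L))
          stop("data inconsistency: patient ", pm$patient[[1L]],
               " has conflicting alt alleles at one position in ",
               h$region$chrom, ":", h$region$start, "-", h$region$end)
        keep <- !duplicated(off)
        pm <- pm[keep, , drop = FALSE]
        off <- off[keep]
      }
      s <- strsplit(ref, "")[[1L]]
      if (!all(s[off + 1L] == pm$ref))
        stop("ref allele mismatch while building block for patient ", pm$patient[[1L]])
      s[off + 1L] <- pm$alt
      paste(s, collapse = "")
    })
    structure(list(hotspot = h, ref_seq = ref, alt_seqs = alt_seqs),
              class = "mutation_block")
  })
}

#' @export
print.mutation_block <- function(x, ...) {
  cat("<mutation_block> ", x$hotspot$region$chrom, ":", x$hotspot$region$start,
      "-", x$hotspot$region$end, " (", x$hotspot$nearest_gene, "): ",
      nchar(x$ref_seq), " bp, ", length(x$alt_seqs), " patient(s)\n", sep = "")
  invisible(x)
}

block_id <- function(block) {
  paste0(block$hotspot$region$chrom, "_", block$hotspot$region$start, "_",
         block$hotspot$region$end)
}

#' Write hotspots as BED (name = nearest gene, score = patient count)
#' @param hotspots List of hotspots.
#' @param path Output BED file.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  df <- do.call(rbind, lapply(hotspots, function(h)
    data.frame(chrom = h$region$chrom, start = h$region$start,
               end = h$region$end, name = h$nearest_gene,
               score = h$n_patients, strand = ".", stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame()
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a mutation block as ref/alt FASTA files
#'
#' Produces `<id>_ref.fa` (single record `ref`) and `<id>_alt.fa` (one
#' record per patient, record ids = patient ids) in `dir`.
#'
#' @param block A `mutation_block`.
#' @param dir Output directory.
#' @export
write_block_fasta <- function(block, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- block_id(block)
  ref <- Biostrings::DNAStringSet(setNames(block$ref_seq, "ref"))
  Biostrings::writeXStringSet(ref, file.path(dir, paste0(id, "_ref.fa")))
  alts <- Biostrings::DNAStringSet(unlist(block$alt_seqs))
  Biostrings::writeXStringSet(alts, file.path(dir, paste0(id, "_alt.fa")))
  invisible(id)
}
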