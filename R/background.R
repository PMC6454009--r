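#' Mutation signatures over k-mer contexts
#'
#' A mutation signature is a probability distribution over (context, alt)
#' pairs: the k-mer sequence context centered on the mutated base (k odd,
#' 1 or 3) and the substituted base.  Within each context the alt
#' probabilities sum to 1 and never include the center base itself.
#' Contexts are used as observed (no pyrimidine-strand collapsing), which
#' keeps signature estimation and signature-based mutation placement
#' internally consistent.
#'
#' @param k Context length (1 or 3).
#' @param table Data frame with columns `context`, `alt`, `probability`.
#' @return An object of class `mutation_signature`.
#' @export
mutation_signature <- function(k, table) {
  stopifnot(k %in% c(1L, 3L))
  need <- c("context", "alt", "probability")
  if (!all(need %in% names(table))) stop("signature table needs columns: ",
                                         paste(need, collapse = " "))
  table$context <- toupper(table$context)
  table$alt <- toupper(table$alt)
  if (any(nchar(table$context) != k)) stop("all contexts must have length k = ", k)
  center <- substr(table$context, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
  if (any(center == table$alt)) stop("alt base must differ from the context center")
  if (any(table$probability < 0)) stop("negative signature probability")
  sums <- tapply(table$probability, table$context, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("per-context alt probabilities must sum to 1; offending context(s): ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  rownames(table) <- NULL
  structure(list(k = as.integer(k), table = table), class = "mutation_signature")
}

#' @export
print.mutation_signature <- function(x, ...) {
  cat("<mutation_signature> k=", x$k, ", ", length(unique(x$table$context)),
      " context(s)\n", sep = "")
  invisible(x)
}

#' @rdname mutation_signature
#' @param path TSV with columns `context`, `alt`, `probability`
#'   (COSMIC-style trinucleotide rows are accepted directly).
#' @export
read_signature <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  k <- nchar(df$context[[1L]])
  mutation_signature(k, df)
}

#' @rdname mutation_signature
#' @param x A `mutation_signature`.
#' @export
write_signature <- function(x, path) {
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical tumor-derived mutation signature from a cohort
#'
#' Tabulates the cohort's observed (context, alt) pairs, taking each
#' mutation's k-mer context from the reference genome, and normalizes the
#' alt frequencies within each context.  Contexts never observed get zero
#' mass.  Mutations whose context would run off a chromosome end or
#' contains `N` are ignored.
#'
#' @param mutations Mutation data frame.
#' @param genome Genome object.
#' @param k Context length (1 or 3; default 3, the COSMIC convention).
#' @return A `mutation_signature`.
#' @export
tumor_signature_from_mutations <- function(mutations, genome, k = 3) {
  stopifnot(k %in% c(1L, 3L))
  if (nrow(mutations) == 0L) stop("cannot derive a signature from an empty mutation list")
  half <- (k - 1L) %/% 2L
  ctx <- vapply(seq_len(nrow(mutations)), function(i) {
    ch <- mutations$chrom[[i]]; p <- mutations$pos[[i]]
    if (p - half < 1L || p + half > nchar(genome[[ch]])) return(NA_character_)
    substr(genome[[ch]], p - half, p + half)
  }, character(1L))
  ok <- !is.na(ctx) & !grepl("[^ACGT]", ctx)
  if (!any(ok)) stop("no mutation has a valid ", k, "-mer context")
  tab <- table(context = ctx[ok], alt = mutations$alt[ok])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, , drop = FALSE]
  tot <- tapply(df$Freq, df$context, sum)
  df$probability <- df$Freq / as.numeric(tot[df$context])
  mutation_signature(k, df[, c("context", "alt", "probability")])
}

#' Sample background window sequences from the analysis regions
#'
#' Draws `n` windows of exactly `length` bp uniformly over all valid start
#' positions pooled across the given regions (constraint: background
#' sequence comes from the same regions as the patient mutation blocks).
#' All-`N` windows are rejected and redrawn.  Deterministic given `seed`.
#'
#' @param regions Regions data frame (0-based half-open).
#' @param genome Genome object.
#' @param length Window length in bp.
#' @param n Number of windows.
#' @param seed Integer seed.
#' @return Character vector of `n` DNA strings.
#' @export
sample_background_regions <- function(regions, genome, length, n, seed) {
  stopifnot(n >= 1)
  wide <- regions[regions$end - regions$start >= length, , drop = FALSE]
  if (nrow(wide) == 0L)
    stop("no analysis region is at least ", length, " bp long; ",
         "cannot draw background windows")
  n_starts <- wide$end - wide$start - length + 1
  cum <- cumsum(n_starts)
  total <- cum[[length(cum)]]
  draw <- function(m) {
    u <- sample.int(total, m, replace = TRUE)
    ri <- findInterval(u - 1, cum) + 1L
    off <- u - c(0, cum)[ri] - 1L
    vapply(seq_len(m), function(j) {
      s0 <- wide$start[[ri[[j]]]] + off[[j]]
      extract_sequence(genome, wide$chrom[[ri[[j]]]], s0, s0 + length)
    }, character(1L))
  }
  set.seed(seed)
  seqs <- draw(n)
  for (tries in 1:50) {
    bad <- !grepl("[ACGT]", seqs)  # all-N windows
    if (!any(bad)) break
    seqs[bad] <- draw(sum(bad))
  }
  if (any(!grepl("[ACGT]", seqs)))
    stop("could not draw non-N background windows from the analysis regions")
  seqs
}

#' Apply uniformly random substitutions to a sequence
#'
#' Chooses `n_mut` distinct non-`N` positions uniformly and replaces each
#' base by one of its 3 alternatives, uniformly.  Deterministic given
#' `seed`.
#'
#' @param seq DNA string.
#' @param n_mut Number of substitutions (0 allowed).
#' @param seed Integer seed.
#' @export
mutate_uniform <- function(seq, n_mut, seed) {
  if (n_mut == 0L) return(seq)
  s <- strsplit(seq, "")[[1L]]
  eligible <- which(s %in% DNA_BASES)
  if (n_mut > length(eligible))
    stop("n_mut = ", n_mut, " exceeds the ", length(eligible),
         " mutable (non-N) positions")
  set.seed(seed)
  pos <- if (length(eligible) == 1L) eligible else sample(eligible, n_mut)
  for (p in pos) s[[p]] <- sample(setdiff(DNA_BASES, s[[p]]), 1L)
  paste(s, collapse = "")
}

#' Apply signature-distributed substitutions to a sequence
#'
#' Repeatedly samples a (context, alt) pair from the signature, then a
#' uniformly chosen not-yet-mutated position of the current sequence whose
#' k-mer context matches, and applies the substitution, until `n_mut`
#' mutations are placed.  Positions are matched against the current
#' (partially mutated) sequence.  Aborts with a context-exhaustion error
#' when the sampled contexts cannot be placed after bounded retries.
#'
#' @param seq DNA string.
#' @param signature A `mutation_signature`.
#' @param n_mut Number of substitutions.
#' @param seed Integer seed.
#' @export
mutate_signature <- function(seq, signature, n_mut, seed) {
  if (n_mut == 0L) return(seq)
  s <- strsplit(seq, "")[[1L]]
  k <- signature$k
  half <- (k - 1L) %/% 2L
  tab <- signature$table
  mutated <- logical(length(s))
  set.seed(seed)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L + 50L * n_mut
  while (placed < n_mut) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("context exhaustion: could not place ", n_mut,
           " signature mutations in the sequence (", placed, " placed)")
    row <- sample.int(nrow(tab), 1L, prob = tab$probability / sum(tab$probability))
    cbases <- strsplit(tab$context[[row]], "")[[1L]]
    centers <- seq.int(1L + half, length(s) - half)
    hit <- !mutated[centers]
    for (d in seq_len(k)) hit <- hit & s[centers + d - 1L - half] == cbases[[d]]
    cand <- centers[hit]
    if (length(cand) == 0L) next
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    s[[p]] <- tab$alt[[row]]
    mutated[[p]] <- TRUE
    placed <- placed + 1L
  }
  paste(s, collapse = "")
}

#' Generate a background set mirroring a patient mutation block
#'
#' Draws `n_blocks` background reference windows of the patient block's
#' length from the pooled analysis regions, and for each window applies
#' the patient block's per-patient mutation-count multiset: one alternate
#' sequence per patient count, carrying exactly that many substitutions
#' under the chosen mutation model.  Sizes and counts therefore match the
#' patient block exactly, and the background delta-dbA sample has the same
#' per-patient structure as the patient sample.
#'
#' @param block A `mutation_block`.
#' @param regions Analysis regions the patient blocks came from.
#' @param genome Genome object.
#' @param model `"uniform"`, `"signature"` or `"tumor_derived"`.
#' @param n_blocks Number of background blocks (default 2000).
#' @param seed Integer seed; the whole set is reproducible from it.
#' @param signature A `mutation_signature` (required for
#'   `model = "signature"`).
#' @param mutations Cohort mutation data frame (required for
#'   `model = "tumor_derived"`; the signature is estimated from it with
#'   [tumor_signature_from_mutations()]).
#' @param k Context length for the tumor-derived signature.
#' @return A `background_set`: list with `block_id`, `model`, `seed`,
#'   `counts` (per-patient mutation counts mirrored), `ref_seqs`
#'   (length `n_blocks`) and `alt_seqs` (list of `n_blocks` character
#'   vectors, one alt per mirrored count).
#' @export
generate_background_set <- function(block, regions, genome,
                                    model = c("uniform", "signature", "tumor_derived"),
                                    n_blocks = 2000, seed = 1,
                                    signature = NULL, mutations = NULL, k = 3) {
  model <- match.arg(model)
  if (model == "signature" && is.null(signature))
    stop("model = 'signature' requires a signature")
  if (model == "tumor_derived") {
    if (is.null(mutations)) stop("model = 'tumor_derived' requires cohort mutations")
    signature <- tumor_signature_from_mutations(mutations, genome, k)
  }
  counts <- vapply(block$alt_seqs, function(a) {
    sum(strsplit(a, "")[[1L]] != strsplit(block$ref_seq, "")[[1L]])
  }, numeric(1L))
  len <- nchar(block$ref_seq)
  refs <- sample_background_regions(regions, genome, len, n_blocks,
                                    seed = derive_seed(seed, 1L))
  alt_seqs <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    alt_seqs[[b]] <- vapply(seq_along(counts), function(j) {
      sub_seed <- derive_seed(seed, 2L, b, j)
      if (model == "uniform") mutate_uniform(refs[[b]], counts[[j]], sub_seed)
      else mutate_signature(refs[[b]], signature, counts[[j]], sub_seed)
    }, character(1L))
  }
  structure(list(block_id = block_id(block), model = model, seed = seed,
                 counts = counts, ref_seqs = refs, alt_seqs = alt_seqs),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat("<background_set> block ", x$block_id, ": ", length(x$ref_seqs),
      " blocks (", x$model, " model), ", length(x$counts),
      " alt(s) per block\n", sep = "")
  invisible(x)
}

#' Audit a background set against its patient block
#'
#' Checks the mirroring constraint: every background pair has the patient
#' block's reference length, and each alternate carries exactly the
#' mirrored patient's mutation count.
#'
#' @param bgset A `background_set`.
#' @param block The `mutation_block` it mirrors.
#' @return Number of violations (0 when the constraint holds).
#' @export
check_background_set <- function(bgset, block) {
  len <- nchar(block$ref_seq)
  counts <- vapply(block$alt_seqs, function(a)
    sum(strsplit(a, "")[[1L]] != strsplit(block$ref_seq, "")[[1L]]), numeric(1L))
  bad <- 0L
  for (b in seq_along(bgset$ref_seqs)) {
    ref <- bgset$ref_seqs[[b]]
    if (nchar(ref) != len) bad <- bad + 1L
    alts <- bgset$alt_seqs[[b]]
    if (length(alts) != length(counts)) { bad <- bad + 1L; next }
    nm <- vapply(alts, function(a)
      sum(strsplit(a, "")[[1L]] != strsplit(ref, "")[[1L]]), numeric(1L))
    bad <- bad + sum(nm != counts)
  }
  bad
}

#' Aggregated delta-dbA of every background alternate sequence
#'
#' Scores a background set the same way patient blocks are scored: for
#' each background block, `dba` of its reference once, then
#' `dba(alt) - dba(ref)` per alternate and PSAM at every chemical
#' potential, aggregated across the ladder by mean.  Each background block
#' gets its own derived shuffle seed shared between its ref and alts.
#'
#' @param bgset A `background_set`.
#' @param psams Named list of PSAMs.
#' @param mus Chemical-potential ladder.
#' @param n_shuffles Shuffles per dbA evaluation.
#' @param seed Integer seed.
#' @param strand `"both"` or `"forward"`.
#' @return List with `deltas` (rows = background alternates, columns =
#'   TFs) and `block_index` (background block of each row).
#' @export
compute_background_deltas <- function(bgset, psams, mus = default_mu_ladder(),
                                      n_shuffles = 100, seed = 1,
                                      strand = c("both", "forward")) {
  strand <- match.arg(strand)
  n_alt <- length(bgset$counts)
  nb <- length(bgset$ref_seqs)
  out <- matrix(0, nrow = nb * n_alt, ncol = length(psams),
                dimnames = list(NULL, names(psams)))
  block_index <- integer(nb * n_alt)
  row <- 0L
  for (b in seq_len(nb)) {
    sb <- derive_seed(seed, 3L, b)
    ref_dba <- dba_matrix(bgset$ref_seqs[[b]], psams, mus, n_shuffles, sb, strand)
    for (j in seq_len(n_alt)) {
      alt_dba <- dba_matrix(bgset$alt_seqs[[b]][[j]], psams, mus, n_shuffles,
                            sb, strand)
      row <- row + 1L
      out[row, ] <- rowMeans(alt_dba - ref_dba)
      block_index[[row]] <- b
    }
  }
  list(deltas = out, block_index = block_index)
}
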