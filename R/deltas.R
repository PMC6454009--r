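#' Per-patient TF binding affinity changes for a mutation block
#'
#' For every patient alternate sequence and every PSAM, computes the
#' shifted differential binding affinity `delta_dba = dba(alt) - dba(ref)`
#' at each chemical potential of the ladder, and aggregates across the
#' ladder by arithmetic mean into one scalar per (patient, TF).  The
#' per-mu tensor is retained for diagnostics and alternative aggregation.
#'
#' Reference and alternate sequences share the same shuffle seed, so a
#' patient whose alternate equals the reference scores exactly zero.
#' PSAMs wider than the block sequence are skipped with a warning.
#'
#' @param block A `mutation_block` from [build_blocks()].
#' @param psams Named list of [psam] objects.
#' @param mus Chemical-potential ladder ([default_mu_ladder()]).
#' @param n_shuffles Shuffles per dbA evaluation.
#' @param seed Integer seed (one shuffle stream per block).
#' @param strand `"both"` or `"forward"`.
#' @return A `delta_set`: list with `block_id`, `tf_ids`, `patient_ids`,
#'   `patient_deltas` (patients x TFs matrix of aggregated delta-dbA) and
#'   `per_mu` (patients x TFs x mus array).
#' @export
compute_block_deltas <- function(block, psams, mus = default_mu_ladder(),
                                 n_shuffles = 100, seed = 1,
                                 strand = c("both", "forward")) {
  strand <- match.arg(strand)
  wide <- vapply(psams, function(p) nrow(p$matrix), numeric(1L)) > nchar(block$ref_seq)
  if (any(wide)) {
    warning("skipping ", sum(wide), " PSAM(s) wider than the block sequence: ",
            paste(names(psams)[wide], collapse = ", "))
    psams <- psams[!wide]
  }
  if (length(psams) == 0L) stop("no PSAM fits the block sequence")
  patients <- names(block$alt_seqs)
  ref_dba <- dba_matrix(block$ref_seq, psams, mus, n_shuffles, seed, strand)
  per_mu <- array(0, dim = c(length(patients), length(psams), length(mus)),
                  dimnames = list(patients, names(psams), as.character(mus)))
  for (i in seq_along(patients)) {
    alt_dba <- dba_matrix(block$alt_seqs[[i]], psams, mus, n_shuffles, seed, strand)
    per_mu[i, , ] <- alt_dba - ref_dba
  }
  agg <- apply(per_mu, c(1L, 2L), mean)
  agg <- matrix(agg, nrow = length(patients),
                dimnames = list(patients, names(psams)))
  structure(list(block_id = block_id(block), tf_ids = names(psams),
                 patient_ids = patients, patient_deltas = agg, per_mu = per_mu),
            class = "delta_set")
}

#' @export
print.delta_set <- function(x, ...) {
  cat("<delta_set> block ", x$block_id, ": ", length(x$patient_ids),
      " patient(s) x ", length(x$tf_ids), " TF(s)\n", sep = "")
  invisible(x)
}

#' Rank TFs by the magnitude of their mean binding change
#'
#' TFs are ordered by descending absolute value of the across-patient mean
#' aggregated delta-dbA; ties are broken lexicographically by TF id.
#'
#' @param delta_set A `delta_set`.
#' @return Character vector of TF ids, most affected first.
#' @export
rank_tfs <- function(delta_set) {
  m <- colMeans(delta_set$patient_deltas)
  ids <- delta_set$tf_ids
  ids[order(-abs(m), ids)]
}

#' Write a delta set as TSV (rows = TFs, columns = patients)
#' @param delta_set A `delta_set`.
#' @param path Output file.
#' @export
write_delta_set <- function(delta_set, path) {
  df <- data.frame(tf = delta_set$tf_ids,
                   t(delta_set$patient_deltas),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
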