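#' Position-specific affinity matrices (PSAMs)
#'
#' A PSAM holds a TF's per-position, per-base binding energies: an M x 4
#' matrix `w` with columns A, C, G, T, where `w[j, a]` is the energy
#' contribution of base `a` at motif position `j`.  Lower energies mean
#' stronger binding in the occupancy model (see [binding_probability()]).
#'
#' The flat-text format is one header line `#TF <name>` followed by M rows
#' of 4 tab-separated energies in A C G T order.
#'
#' @param tf_name TF name.
#' @param matrix Numeric M x 4 energy matrix, M >= 4, finite entries.
#' @param source Optional provenance id.
#' @return An object of class `psam`.
#' @export
psam <- function(tf_name, matrix, source = NA_character_) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PSAM matrix must have 4 columns (A C G T)")
  if (nrow(matrix) < 4L) stop("PSAM must have at least 4 positions")
  if (!all(is.finite(matrix))) stop("PSAM entries must be finite")
  colnames(matrix) <- DNA_BASES
  structure(list(tf_name = tf_name, matrix = matrix, source = source),
            class = "psam")
}

#' @export
print.psam <- function(x, ...) {
  cat("<psam> ", x$tf_name, ": ", nrow(x$matrix), " positions\n", sep = "")
  invisible(x)
}

#' @rdname psam
#' @param path A PSAM flat-text file.
#' @export
read_psam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L || !grepl("^#TF\\s+", lines[[1L]]))
    stop("PSAM file ", path, " must start with a '#TF <name>' header line")
  name <- sub("^#TF\\s+", "", lines[[1L]])
  body <- lines[-1L]
  body <- body[!startsWith(body, "#")]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(l, "\\s+")[[1L]])))
  if (any(is.na(m)) || ncol(m) != 4L)
    stop("PSAM file ", path, ": expected rows of 4 numeric energies")
  psam(name, m, source = basename(path))
}

#' @rdname psam
#' @export
write_psam <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#TF ", x$tf_name), con)
  write.table(format(x$matrix, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a directory of PSAM files
#' @param dir Directory containing `*.psam` (or any flat-text PSAM) files.
#' @return Named list of `psam` objects (names = TF names).
#' @export
read_psam_collection <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no PSAM files found in ", dir)
  ps <- lapply(files, read_psam)
  names(ps) <- vapply(ps, `[[`, character(1L), "tf_name")
  if (anyDuplicated(names(ps))) stop("duplicate TF names in PSAM collection ", dir)
  ps
}

#' Build a PSAM from a consensus sequence
#'
#' Each consensus base gets energy `energy` (negative = favorable) and all
#' other bases `other`.  Used by the fixture generator, where it gives
#' controllable, interpretable effect sizes.
#'
#' @param tf_name TF name.
#' @param consensus Consensus DNA string (length >= 4).
#' @param energy Energy of the consensus base at each position.
#' @param other Energy of non-consensus bases.
#' @export
psam_from_consensus <- function(tf_name, consensus, energy = -2, other = 0) {
  bases <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(bases %in% DNA_BASES)) stop("consensus must be over A/C/G/T")
  m <- matrix(other, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  for (j in seq_along(bases)) m[j, bases[[j]]] <- energy
  psam(tf_name, m)
}

#' Build a random graded PSAM
#'
#' Draws, for each position, a random base-preference profile (gamma
#' variates normalized to the position's best base) and scales it to the
#' given consensus energy.  Unlike [psam_from_consensus()], the resulting
#' energies are graded: non-preferred bases get intermediate penalties,
#' as in experimentally derived affinity matrices.  Used for the decoy
#' TFs of synthetic fixtures; draws from R's RNG stream.
#'
#' @param tf_name TF name.
#' @param width Motif width.
#' @param energy Energy of the preferred base at each position.
#' @param shape Gamma shape controlling position sharpness (smaller =
#'   sharper preferences).
#' @export
psam_random <- function(tf_name, width = 8, energy = -2, shape = 0.7) {
  g <- matrix(stats::rgamma(width * 4L, shape = shape, rate = 1), width, 4L)
  w <- energy * g / apply(g, 1L, max)
  psam(tf_name, w)
}

# exp(w) matrix used by the compiled scanner (precomputed-exponent identity)
psam_expw <- function(p) exp(unname(p$matrix))
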