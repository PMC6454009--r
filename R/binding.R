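#' Default chemical-potential ladder
#'
#' Chemical potentials (mu) represent the TF's effective nuclear
#' concentration in the occupancy logistic: lower mu means a scarcer TF
#' and sharper discrimination between strong and weak sites.  The default
#' ladder spans the dynamic range over which verified regulatory variants
#' alter occupancy.
#'
#' @return Numeric vector `c(0, -10, -13, -15, -18, -20)`.
#' @export
default_mu_ladder <- function() c(0, -10, -13, -15, -18, -20)

#' TF binding energy of a single window
#'
#' Sums the PSAM energies of the window's bases under the independent-site
#' approximation: `E = sum_j w[j, S_j]`.  Windows containing `N` return
#' `Inf`, the zero-occupancy sentinel.
#'
#' @param window DNA string of length equal to the PSAM width.
#' @param psam A [psam] object.
#' @return Scalar binding energy.
#' @export
binding_energy <- function(window, psam) {
  M <- nrow(psam$matrix)
  if (nchar(window) != M)
    stop("window length ", nchar(window), " does not match PSAM width ", M)
  bases <- strsplit(toupper(window), "")[[1L]]
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx)) return(Inf)
  sum(psam$matrix[cbind(seq_len(M), idx)])
}

#' TF occupancy of a sequence (reference implementation)
#'
#' Statistical-mechanics occupancy summed over all sliding windows:
#' `P = sum_i 1 / (1 + exp(E_i - mu))` where `E_i` is the binding energy
#' of the window starting at `i`.  With `strand = "both"` the same sum
#' over the reverse complement of `seq` is added.  Windows containing `N`
#' contribute zero.
#'
#' This is the plain double-loop reference; [binding_probability_fast()]
#' computes the identical quantity with precomputed exponents in C++.
#'
#' @param seq DNA string, length >= PSAM width.
#' @param psam A [psam] object.
#' @param mu Chemical potential.
#' @param strand `"both"` (default; occupancy is strand-agnostic) or
#'   `"forward"`.
#' @return Scalar expected occupancy (0 to number of windows scanned).
#' @export
binding_probability <- function(seq, psam, mu, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  M <- nrow(psam$matrix)
  if (nchar(seq) < M) stop("sequence shorter than the motif width ", M)
  scan1 <- function(s) {
    total <- 0
    for (i in seq_len(nchar(s) - M + 1L)) {
      e <- binding_energy(substr(s, i, i + M - 1L), psam)
      if (is.finite(e)) total <- total + 1 / (1 + exp(e - mu))
    }
    total
  }
  p <- scan1(seq)
  if (strand == "both") p <- p + scan1(revcomp(seq))
  p
}

#' @describeIn binding_probability Identical contract, computed by the
#'   compiled scanner: `exp(w[j,a])` and `exp(-mu)` are precomputed once
#'   per (PSAM, mu) so no exponent is evaluated inside the sliding window.
#' @export
binding_probability_fast <- function(seq, psam, mu, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  as.numeric(cpp_occupancy(seq, psam_expw(psam), mu, strand == "both"))
}

# occupancy across a whole mu ladder in one compiled call
occupancy_ladder <- function(seq, psam, mus, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  setNames(as.numeric(cpp_occupancy(seq, psam_expw(psam), mus, strand == "both")), mus)
}

#' Reverse complement of a DNA string
#' @param seq DNA string (may contain N).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Differential binding affinity (dbA) of a sequence
#'
#' Occupancy above background: the sequence's occupancy minus the mean
#' occupancy of `n_shuffles` mononucleotide-composition-preserving
#' shuffles of the same sequence, floored at zero.  Deterministic given
#' `seed` (shuffles use a private RNG stream, not R's).
#'
#' @inheritParams binding_probability
#' @param n_shuffles Number of composition-preserving shuffles (>= 1).
#' @param seed Integer seed for the shuffle stream.
#' @return Scalar dbA >= 0.
#' @export
dba <- function(seq, psam, mu, n_shuffles = 100, seed = 1,
                strand = c("both", "forward")) {
  strand <- match.arg(strand)
  m <- cpp_dba_multi(seq, list(psam_expw(psam)), mu, as.integer(n_shuffles),
                     as.integer(seed), strand == "both")
  as.numeric(m[1L, 1L])
}

#' Shifted differential binding affinity between two sequences
#'
#' `delta_dba = dba(alt) - dba(ref)`, the measure of a mutation's binding
#' affinity change: positive values indicate creation of binding sites,
#' negative values destruction of existing sites.  The same PSAM, mu and
#' shuffle seed are used on both sides, so `alt == ref` gives exactly 0
#' and the quantity is antisymmetric.
#'
#' @param ref_seq,alt_seq Reference and alternate DNA strings.
#' @inheritParams dba
#' @export
delta_dba <- function(ref_seq, alt_seq, psam, mu, n_shuffles = 100, seed = 1,
                      strand = c("both", "forward")) {
  strand <- match.arg(strand)
  dba(alt_seq, psam, mu, n_shuffles, seed, strand) -
    dba(ref_seq, psam, mu, n_shuffles, seed, strand)
}

# dbA for one sequence across a PSAM collection and mu ladder: n_tf x n_mu.
# The shuffle stream is shared across PSAMs and mus (one set of shuffled
# sequences per call), which is what makes block scoring tractable.
dba_matrix <- function(seq, psams, mus, n_shuffles, seed,
                       strand = c("both", "forward")) {
  strand <- match.arg(strand)
  expws <- lapply(psams, psam_expw)
  m <- cpp_dba_multi(seq, unname(expws), mus, as.integer(n_shuffles),
                     as.integer(seed), strand == "both")
  dimnames(m) <- list(names(psams), as.character(mus))
  m
}
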