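#' Conjoint triad spectrum of a protein sequence
#'
#' Reduces the sequence to the seven physicochemical groups, slides a
#' window of three residues along it, and counts each of the 343 ordered
#' group triads.  Counts are normalised by the number of windows,
#' `L - 2`, so the spectrum sums to 1.  Triads are ordered
#' lexicographically: triad `(g1, g2, g3)` sits at index
#' `49*(g1-1) + 7*(g2-1) + g3`.
#'
#' @param seq A single sanitized protein sequence (see [sanitize_seq()]).
#' @return Numeric vector of length 343 with names `t<g1><g2><g3>`;
#'   attribute `counts` holds the raw window counts.
#' @examples
#' v <- encode_ctf_protein("AGVC")
#' v[v > 0]  # AGV -> triad (1,1,1), GVC -> triad (1,1,7), each 0.5
#' @export
encode_ctf_protein <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  g <- protein_group7(strsplit(seq, "")[[1]])
  L <- length(g)
  if (L < 3L) stop("sequence too short for triads (need L >= 3, got ", L, ")")
  idx <- 49L * (g[1:(L - 2)] - 1L) + 7L * (g[2:(L - 1)] - 1L) + g[3:L]
  counts <- tabulate(idx, nbins = 343L)
  grid <- expand.grid(g3 = 1:7, g2 = 1:7, g1 = 1:7)[, 3:1]
  nm <- paste0("t", grid$g1, grid$g2, grid$g3)
  structure(setNames(counts / (L - 2), nm), counts = counts)
}

#' 4-mer spectrum of an RNA sequence
#'
#' Counts every window of four successive bases over `{A, C, G, U}`
#' (256 4-mer types, lexicographic order).  The published normalisation
#' divides the counts by `N - 2` (`denominator = "published"`, the default);
#' the true window count is `N - 3`, available as
#' `denominator = "exact"`, under which the spectrum sums to 1.
#'
#' @param seq A single sanitized RNA sequence.
#' @param denominator `"published"` (divide by `N - 2`) or `"exact"`
#'   (divide by `N - 3`).
#' @return Numeric vector of length 256 with names `k<4-mer>`;
#'   attribute `counts` holds the raw window counts.
#' @examples
#' encode_ctf_rna("ACGU")[["kACGU"]]                        # 0.5
#' encode_ctf_rna("ACGU", denominator = "exact")[["kACGU"]] # 1
#' @export
encode_ctf_rna <- function(seq, denominator = c("published", "exact")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  denominator <- match.arg(denominator)
  b <- rna_vertex(strsplit(seq, "")[[1]])
  N <- length(b)
  if (N < 4L) stop("sequence too short for 4-mers (need N >= 4, got ", N, ")")
  idx <- 64L * (b[1:(N - 3)] - 1L) + 16L * (b[2:(N - 2)] - 1L) +
    4L * (b[3:(N - 1)] - 1L) + b[4:N]
  counts <- tabulate(idx, nbins = 256L)
  grid <- expand.grid(b4 = RNA4, b3 = RNA4, b2 = RNA4, b1 = RNA4,
                      stringsAsFactors = FALSE)[, 4:1]
  nm <- paste0("k", grid$b1, grid$b2, grid$b3, grid$b4)
  denom <- if (denominator == "published") N - 2L else N - 3L
  structure(setNames(counts / denom, nm), counts = counts)
}

#' Amino-acid composition
#'
#' Frequencies of the 20 standard amino acids in alphabetical order.
#'
#' @param seq A single sanitized protein sequence.
#' @return Numeric vector of length 20 summing to 1.
#' @export
encode_aac <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  r <- strsplit(seq, "")[[1]]
  if (length(r) == 0L) stop("empty sequence")
  protein_group7(r)  # validates the alphabet
  counts <- table(factor(r, levels = AA20))
  setNames(as.numeric(counts) / length(r), AA20)
}

#' Nucleotide composition
#'
#' Frequencies of A, C, G, U.
#'
#' @param seq A single sanitized RNA sequence.
#' @return Numeric vector of length 4 summing to 1.
#' @export
encode_nc <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  b <- strsplit(seq, "")[[1]]
  if (length(b) == 0L) stop("empty sequence")
  rna_vertex(b)
  counts <- table(factor(b, levels = RNA4))
  setNames(as.numeric(counts) / length(b), RNA4)
}
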