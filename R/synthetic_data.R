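#' Configuration for the synthetic benchmark generator
#'
#' Describes a labelled benchmark of protein-RNA pairs whose
#' interaction label is determined by sequence content: a pair is
#' interacting if and only if the protein carries `protein_motif` AND
#' the RNA carries `rna_motif`.  Motifs are implanted at uniformly
#' random positions, overwriting the uniform background, so
#' composition features carry only weak signal and k-mer/CGR encoders
#' must capture ordering.
#'
#' @param n_pairs Number of pairs.
#' @param positive_fraction Fraction of interacting pairs before label
#'   noise.
#' @param protein_length_range,rna_length_range Integer length ranges
#'   (inclusive) for the background sequences.
#' @param protein_motif Amino-acid motif, length >= 3 (visible to the
#'   triad encoder).
#' @param rna_motif Base motif over ACGU, length >= 4 (visible to the
#'   4-mer encoder).
#' @param noise_rate Probability that a label is flipped.
#' @param seed Integer seed; the benchmark is fully determined by it.
#' @return A list of class `rpi_sim_config`.
#' @export
synthetic_config <- function(n_pairs = 200, positive_fraction = 0.5,
                             protein_length_range = c(50, 150),
                             rna_length_range = c(40, 120),
                             protein_motif = "CWKDEMH",
                             rna_motif = "GACUCG",
                             noise_rate = 0, seed = 1) {
  protein_motif <- sanitize_seq(protein_motif, "protein", strict = TRUE)
  rna_motif <- sanitize_seq(rna_motif, "rna", strict = TRUE)
  if (nchar(protein_motif) < 3L) stop("protein motif must be at least 3 residues")
  if (nchar(rna_motif) < 4L) stop("RNA motif must be at least 4 bases")
  if (nchar(protein_motif) > min(protein_length_range)) {
    stop("protein motif longer than the minimum protein length")
  }
  if (nchar(rna_motif) > min(rna_length_range)) {
    stop("RNA motif longer than the minimum RNA length")
  }
  stopifnot(n_pairs >= 2, positive_fraction > 0, positive_fraction < 1,
            noise_rate >= 0, noise_rate < 1)
  structure(
    list(n_pairs = as.integer(n_pairs),
         positive_fraction = positive_fraction,
         protein_length_range = as.integer(protein_length_range),
         rna_length_range = as.integer(rna_length_range),
         protein_motif = protein_motif, rna_motif = rna_motif,
         noise_rate = noise_rate, seed = as.integer(seed)),
    class = "rpi_sim_config"
  )
}

.random_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

.implant <- function(seq, motif) {
  L <- nchar(seq)
  k <- nchar(motif)
  pos <- sample.int(L - k + 1L, 1L)
  paste0(substr(seq, 1, pos - 1L), motif, substr(seq, pos + k, L))
}

# Draw a background sequence that does NOT contain `avoid` (regenerate
# on the rare accidental hit).
.background_without <- function(range, alphabet, avoid) {
  repeat {
    s <- .random_seq(sample(range[1]:range[2], 1L), alphabet)
    if (!grepl(avoid, s, fixed = TRUE)) return(s)
  }
}

#' Generate a synthetic protein-RNA interaction benchmark
#'
#' Draws `n_pairs` protein/RNA pairs with i.i.d. uniform background
#' residues.  Interacting pairs carry both motifs; non-interacting
#' pairs carry at most one (the protein motif only, the RNA motif
#' only, or neither, in roughly equal shares).  The true label follows
#' the motif rule exactly; `noise_rate` then flips each label
#' independently.
#'
#' @param config An [synthetic_config()] object.
#' @return A list of class `rpi_sim`: `proteins` and `rnas` (named
#'   vectors), `pairs` (`data.frame` with `protein_id`, `rna_id`,
#'   `label`), and `truth` (true pre-noise labels, flip indicators and
#'   the config).
#' @export
generate_pairs <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "rpi_sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  n_pos <- as.integer(round(n * config$positive_fraction))
  is_pos <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))
  pm <- config$protein_motif
  rm_ <- config$rna_motif
  proteins <- character(n)
  rnas <- character(n)
  for (i in seq_len(n)) {
    if (is_pos[i]) {
      proteins[i] <- .implant(
        .random_seq(sample(config$protein_length_range[1]:config$protein_length_range[2], 1L), AA20), pm)
      rnas[i] <- .implant(
        .random_seq(sample(config$rna_length_range[1]:config$rna_length_range[2], 1L), RNA4), rm_)
    } else {
      kind <- sample(c("protein_only", "rna_only", "neither"), 1L)
      proteins[i] <- if (kind == "protein_only") {
        .implant(.random_seq(sample(config$protein_length_range[1]:config$protein_length_range[2], 1L), AA20), pm)
      } else {
        .background_without(config$protein_length_range, AA20, pm)
      }
      rnas[i] <- if (kind == "rna_only") {
        .implant(.random_seq(sample(config$rna_length_range[1]:config$rna_length_range[2], 1L), RNA4), rm_)
      } else {
        .background_without(config$rna_length_range, RNA4, rm_)
      }
    }
  }
  names(proteins) <- sprintf("prot_%04d", seq_len(n))
  names(rnas) <- sprintf("rna_%04d", seq_len(n))
  true_label <- as.integer(grepl(pm, proteins, fixed = TRUE) &
                             grepl(rm_, rnas, fixed = TRUE))
  stopifnot(identical(true_label, as.integer(is_pos)))
  flipped <- runif(n) < config$noise_rate
  label <- ifelse(flipped, 1L - true_label, true_label)
  structure(
    list(proteins = proteins, rnas = rnas,
         pairs = data.frame(protein_id = names(proteins),
                            rna_id = names(rnas),
                            label = label, stringsAsFactors = FALSE),
         truth = list(true_label = true_label, flipped = flipped,
                      config = unclass(config))),
    class = "rpi_sim"
  )
}

#' @export
print.rpi_sim <- function(x, ...) {
  cat("<rpi_sim> ", nrow(x$pairs), " pairs (",
      sum(x$pairs$label == 1L), " positive); seed ",
      x$truth$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic benchmark to disk
#'
#' Emits `protein.fasta`, `rna.fasta`, `pairs.tsv` and a ground-truth
#' manifest `truth.json`; byte-identical across runs with the same
#' config.
#'
#' @param sim An `rpi_sim` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rpi_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteins, file.path(dir, "protein.fasta"))
  write_fasta(sim$rnas, file.path(dir, "rna.fasta"))
  write_pairs(sim$pairs, file.path(dir, "pairs.tsv"))
  jsonlite::write_json(
    list(true_label = sim$truth$true_label,
         flipped = sim$truth$flipped,
         config = sim$truth$config),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
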