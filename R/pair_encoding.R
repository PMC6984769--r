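#' The five feature sets
#'
#' Canonical names and dimensionalities of the supported per-pair
#' feature sets: the AAC+NC composition baseline (20 + 4 = 24), the
#' conjoint triad set (343 protein + 256 RNA = 599), the chaos-game set
#' (24 + 16 = 40), and their combinations (639 and 663).
#'
#' @return A `data.frame` with columns `name` and `dim`.
#' @export
feature_sets <- function() {
  data.frame(
    name = c("AAC+NC", "CTF", "CGR", "CTF+CGR", "CTF+CGR+AAC+NC"),
    dim = c(24L, 599L, 40L, 639L, 663L),
    stringsAsFactors = FALSE
  )
}

# Normalise a feature-set name: case-insensitive, "+"-separated.
.match_feature_set <- function(name) {
  fs <- feature_sets()
  hit <- match(toupper(gsub("\\s", "", name)), fs$name)
  if (is.na(hit)) {
    stop("unknown feature set '", name, "'; valid sets: ",
         paste(fs$name, collapse = ", "))
  }
  fs[hit, ]
}

# Which feature families a set includes, in canonical family order
# (CTF, CGR, AAC, NC); within a family the protein block precedes the
# RNA block.
.feature_families <- function(name) {
  parts <- strsplit(.match_feature_set(name)$name, "+", fixed = TRUE)[[1]]
  intersect(c("CTF", "CGR", "AAC", "NC"), parts)
}

#' Encode one protein-RNA pair as a feature vector
#'
#' Concatenates the selected per-sequence encodings in a fixed order:
#' families CTF, CGR, AAC, NC (as included by the feature set), the
#' protein block before the RNA block inside each family.  Column names
#' are stable: `p_ctf_000..p_ctf_342`, `r_ctf_000..r_ctf_255`,
#' `p_cgr_01..p_cgr_24`, `r_cgr_01..r_cgr_16`, `p_aac_<AA>`,
#' `r_nc_<base>`.
#'
#' @param protein,rna Single sanitized sequences.
#' @param feature_set One of `"AAC+NC"`, `"CTF"`, `"CGR"`, `"CTF+CGR"`,
#'   `"CTF+CGR+AAC+NC"` (case-insensitive).
#' @param rna_denominator Passed to [encode_ctf_rna()].
#' @param twelve_map Optional 12-group override for the protein CGR.
#' @return Named numeric vector of the set's dimension (24, 599, 40,
#'   639 or 663).
#' @export
encode_pair <- function(protein, rna, feature_set = "CTF+CGR",
                        rna_denominator = c("published", "exact"),
                        twelve_map = NULL) {
  rna_denominator <- match.arg(rna_denominator)
  fam <- .feature_families(feature_set)
  blocks <- list()
  if ("CTF" %in% fam) {
    p <- encode_ctf_protein(protein)
    r <- encode_ctf_rna(rna, denominator = rna_denominator)
    blocks$p_ctf <- setNames(as.numeric(p), sprintf("p_ctf_%03d", 0:342))
    blocks$r_ctf <- setNames(as.numeric(r), sprintf("r_ctf_%03d", 0:255))
  }
  if ("CGR" %in% fam) {
    p <- encode_cgr_protein(protein, twelve_map = twelve_map)
    r <- encode_cgr_rna(rna)
    blocks$p_cgr <- setNames(as.numeric(p), sprintf("p_cgr_%02d", 1:24))
    blocks$r_cgr <- setNames(as.numeric(r), sprintf("r_cgr_%02d", 1:16))
  }
  if ("AAC" %in% fam) {
    blocks$p_aac <- setNames(as.numeric(encode_aac(protein)),
                             paste0("p_aac_", AA20))
  }
  if ("NC" %in% fam) {
    blocks$r_nc <- setNames(as.numeric(encode_nc(rna)),
                            paste0("r_nc_", RNA4))
  }
  out <- unlist(blocks, use.names = TRUE)
  names(out) <- sub("^[^.]+\\.", "", names(out))
  expected <- .match_feature_set(feature_set)$dim
  stopifnot(length(out) == expected)
  out
}

#' Build the design matrix for a set of pairs
#'
#' Encodes every pair in `pairs` under the chosen feature set.  Each
#' distinct sequence is encoded once and reused, which is guaranteed to
#' give results identical to per-pair recomputation.
#'
#' @param pairs `data.frame` with columns `protein_id`, `rna_id` and
#'   optionally `label` (see [read_pairs()]).
#' @param proteins,rnas Named character vectors of sanitized sequences,
#'   e.g. from [read_fasta()].
#' @inheritParams encode_pair
#' @return An object of class `rpi_matrix`: a list with `x` (numeric
#'   matrix, one row per pair, stable column names), `labels` (integer
#'   vector or `NULL`), `pairs`, and `feature_set`.
#' @export
build_matrix <- function(pairs, proteins, rnas, feature_set = "CTF+CGR",
                         rna_denominator = c("published", "exact"),
                         twelve_map = NULL) {
  rna_denominator <- match.arg(rna_denominator)
  fs <- .match_feature_set(feature_set)
  missing_p <- setdiff(unique(pairs$protein_id), names(proteins))
  missing_r <- setdiff(unique(pairs$rna_id), names(rnas))
  if (length(missing_p) || length(missing_r)) {
    stop("pair table references absent sequence ids: ",
         paste(c(missing_p, missing_r), collapse = ", "))
  }
  fam <- .feature_families(feature_set)
  encode_protein <- function(s) {
    unlist(c(
      if ("CTF" %in% fam) list(as.numeric(encode_ctf_protein(s))),
      if ("CGR" %in% fam) list(as.numeric(encode_cgr_protein(s, twelve_map = twelve_map))),
      if ("AAC" %in% fam) list(as.numeric(encode_aac(s)))
    ))
  }
  encode_rna <- function(s) {
    unlist(c(
      if ("CTF" %in% fam) list(as.numeric(encode_ctf_rna(s, denominator = rna_denominator))),
      if ("CGR" %in% fam) list(as.numeric(encode_cgr_rna(s))),
      if ("NC" %in% fam) list(as.numeric(encode_nc(s)))
    ))
  }
  p_ids <- unique(pairs$protein_id)
  r_ids <- unique(pairs$rna_id)
  p_cache <- tryCatch(
    lapply(setNames(p_ids, p_ids), function(i) encode_protein(proteins[[i]])),
    error = function(e) stop("encoding a protein failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  r_cache <- tryCatch(
    lapply(setNames(r_ids, r_ids), function(i) encode_rna(rnas[[i]])),
    error = function(e) stop("encoding an RNA failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  # Reassemble per pair in canonical family order (protein block then
  # RNA block within each family).
  template <- encode_pair(proteins[[pairs$protein_id[1]]],
                          rnas[[pairs$rna_id[1]]],
                          feature_set = feature_set,
                          rna_denominator = rna_denominator,
                          twelve_map = twelve_map)
  fam_dims_p <- c(CTF = 343L, CGR = 24L, AAC = 20L)[intersect(fam, c("CTF", "CGR", "AAC"))]
  fam_dims_r <- c(CTF = 256L, CGR = 16L, NC = 4L)[intersect(fam, c("CTF", "CGR", "NC"))]
  assemble <- function(pv, rv) {
    po <- ro <- 0L
    out <- numeric(0)
    for (f in fam) {
      if (f %in% c("CTF", "CGR", "AAC")) {
        k <- fam_dims_p[[f]]
        out <- c(out, pv[(po + 1):(po + k)])
        po <- po + k
      }
      if (f %in% c("CTF", "CGR", "NC")) {
        k <- fam_dims_r[[f]]
        out <- c(out, rv[(ro + 1):(ro + k)])
        ro <- ro + k
      }
    }
    out
  }
  x <- t(vapply(seq_len(nrow(pairs)), function(i) {
    assemble(p_cache[[pairs$protein_id[i]]], r_cache[[pairs$rna_id[i]]])
  }, numeric(fs$dim)))
  colnames(x) <- names(template)
  rownames(x) <- paste(pairs$protein_id, pairs$rna_id, sep = ":")
  structure(
    list(x = x,
         labels = if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL,
         pairs = pairs[, intersect(c("protein_id", "rna_id", "label"), names(pairs))],
         feature_set = fs$name),
    class = "rpi_matrix"
  )
}

#' @export
print.rpi_matrix <- function(x, ...) {
  cat("<rpi_matrix> ", nrow(x$x), " pairs x ", ncol(x$x),
      " features (", x$feature_set, ")",
      if (!is.null(x$labels)) {
        sprintf("; labels: %d positive / %d negative",
                sum(x$labels == 1L), sum(x$labels == 0L))
      } else {
        "; unlabelled"
      }, "\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' One row per pair with `protein_id`, `rna_id`, optional `label`, then
#' the named feature columns.
#'
#' @param m An `rpi_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "rpi_matrix"))
  df <- cbind(m$pairs, as.data.frame(m$x, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
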