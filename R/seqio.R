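#' @importFrom stats predict runif setNames
#' @importFrom utils read.delim write.table head
NULL

#' The 20 standard amino acids, alphabetical one-letter order
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The RNA alphabet
#' @keywords internal
RNA4 <- c("A", "C", "G", "U")

# Seven physicochemical groups used by the conjoint triad encoding,
# in their conventional order: {AGV} {ILFP} {YMTS} {HNQW} {RK} {DE} {C}.
.GROUPS7 <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C")
)

# Default 12-class partition for the 12-gon chaos game, built by
# splitting the seven conjoint-triad groups into twelve physicochemical
# classes.  The partition is configuration, not
# method: any total map of the 20 amino acids onto vertices 1..12 gives a
# valid CGR-24 encoding, and users can supply their own (see
# `twelve_group_map`).
.GROUPS12 <- list(
  "A", "G", "V",
  c("I", "L"), c("F", "P"),
  c("Y", "W"), "M", c("T", "S"),
  c("H", "N", "Q"),
  c("R", "K"), c("D", "E"), "C"
)

.map_from_groups <- function(groups) {
  m <- integer(0)
  for (k in seq_along(groups)) m[groups[[k]]] <- k
  m[order(names(m))]
}

.SEVEN_MAP <- .map_from_groups(.GROUPS7)
.TWELVE_MAP <- .map_from_groups(.GROUPS12)

#' Seven-group index of amino-acid residues
#'
#' Maps each standard amino acid to its conjoint-triad group, with the
#' groups `{AGV} {ILFP} {YMTS} {HNQW} {RK} {DE} {C}` numbered 1 to 7 in
#' that order.
#'
#' @param residue Character vector of one-letter amino-acid codes.
#' @return Integer vector of group indices in `1..7`.
#' @examples
#' protein_group7(c("V", "K", "C"))  # 1 5 7
#' @export
protein_group7 <- function(residue) {
  residue <- toupper(residue)
  bad <- !(residue %in% AA20)
  if (any(bad)) {
    stop("unknown amino acid residue(s): ",
         paste(unique(residue[bad]), collapse = ", "))
  }
  unname(.SEVEN_MAP[residue])
}

#' Twelve-group vertex index of amino-acid residues
#'
#' Maps each standard amino acid to a vertex of the 12-gon used by the
#' protein chaos game representation.  The default partition refines the
#' seven conjoint-triad groups into
#' `{A} {G} {V} {IL} {FP} {YW} {M} {TS} {HNQ} {RK} {DE} {C}`; pass
#' `map` to reproduce any other published 12-class scheme.
#'
#' @param residue Character vector of one-letter amino-acid codes.
#' @param map Optional named integer vector (names = the 20 amino acids,
#'   values in `1..12`) overriding the default partition.
#' @return Integer vector of vertex indices in `1..12`.
#' @export
protein_group12 <- function(residue, map = NULL) {
  m <- if (is.null(map)) .TWELVE_MAP else validate_twelve_map(map)
  residue <- toupper(residue)
  bad <- !(residue %in% names(m))
  if (any(bad)) {
    stop("unknown amino acid residue(s): ",
         paste(unique(residue[bad]), collapse = ", "))
  }
  unname(m[residue])
}

#' Validate a user-supplied 12-group amino-acid map
#'
#' @param map Named integer vector; names must cover the 20 standard
#'   amino acids and values must use every index in `1..12`.
#' @return The map, normalised to integer and alphabetical name order.
#' @export
validate_twelve_map <- function(map) {
  map <- setNames(as.integer(map), toupper(names(map)))
  if (!setequal(names(map), AA20)) {
    stop("twelve-group map must be defined for exactly the 20 standard amino acids")
  }
  if (!setequal(unique(unname(map)), 1:12)) {
    stop("twelve-group map values must cover every vertex index 1..12")
  }
  map[order(names(map))]
}

#' Read a 12-group map from a JSON file
#'
#' The file holds a single object mapping one-letter amino-acid codes to
#' vertex indices, e.g. `{"A": 1, "C": 12, ...}`.
#'
#' @param path Path to a JSON file.
#' @return A validated named integer vector (see [validate_twelve_map()]).
#' @export
read_twelve_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_twelve_map(unlist(obj))
}

#' Vertex index of RNA bases
#'
#' A, C, G, U map to square vertices 1..4.
#'
#' @param base Character vector of bases.
#' @return Integer vector in `1..4`.
#' @export
rna_vertex <- function(base) {
  base <- toupper(base)
  idx <- match(base, RNA4)
  if (anyNA(idx)) {
    stop("unknown RNA base(s): ", paste(unique(base[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Sanitize a raw sequence string
#'
#' Uppercases the input; for RNA additionally maps `T` to `U` (DNA-style
#' FASTA is common).  Characters still outside the alphabet are dropped
#' with a warning by default, or raise an error in strict mode.
#' Dropping joins the flanking residues, so k-mer windows are formed on
#' the cleaned string.
#'
#' @param seq Character vector of raw sequences.
#' @param moltype `"protein"` or `"rna"`.
#' @param strict If `TRUE`, any out-of-alphabet character is an error.
#' @param id Optional identifier(s) used in messages.
#' @return Character vector of cleaned sequences.
#' @export
sanitize_seq <- function(seq, moltype = c("protein", "rna"),
                         strict = FALSE, id = NULL) {
  moltype <- match.arg(moltype)
  seq <- toupper(seq)
  if (moltype == "rna") seq <- gsub("T", "U", seq, fixed = TRUE)
  alphabet <- if (moltype == "protein") AA20 else RNA4
  pattern <- paste0("[^", paste(alphabet, collapse = ""), "]")
  has_bad <- grepl(pattern, seq)
  if (any(has_bad)) {
    who <- if (is.null(id)) which(has_bad) else id[has_bad]
    if (strict) {
      stop("non-standard characters in sequence(s): ",
           paste(who, collapse = ", "))
    }
    warning("dropping non-standard characters from sequence(s): ",
            paste(who, collapse = ", "))
    seq <- gsub(pattern, "", seq)
  }
  seq
}

#' Read sequences from a FASTA file
#'
#' Parses a FASTA file, takes each identifier from its header up to the
#' first whitespace, and applies [sanitize_seq()] to every record.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"` or `"rna"`.
#' @param strict Passed to [sanitize_seq()].
#' @return Named character vector of sequences with attribute
#'   `moltype`; order follows the file.
#' @export
read_fasta <- function(path, moltype = c("protein", "rna"), strict = FALSE) {
  moltype <- match.arg(moltype)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- sanitize_seq(as.character(set), moltype, strict = strict, id = ids)
  if (any(!nzchar(seqs))) {
    stop("empty sequence ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  structure(setNames(unname(seqs), ids), moltype = moltype)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein-RNA pair table
#'
#' Reads a delimited text file with columns `protein_id`, `rna_id` and
#' an optional binary `label`.  A header row is detected and skipped if
#' its third field is not 0/1 (or, for two-column files, if the first
#' line equals `protein_id<sep>rna_id`).  A file must be entirely
#' labelled (training mode) or entirely unlabelled (prediction mode).
#'
#' @param path Path to a tab- (or comma-) separated file.
#' @param sep Field separator, default tab.
#' @return A `data.frame` with columns `protein_id`, `rna_id` and,
#'   when present, integer `label` in `{0, 1}`.
#' @export
read_pairs <- function(path, sep = "\t") {
  raw <- read.delim(path, header = FALSE, sep = sep,
                    colClasses = "character", strip.white = TRUE,
                    blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) stop("empty pair table: ", path)
  if (ncol(raw) < 2L || ncol(raw) > 3L) {
    stop("pair table must have 2 or 3 columns, found ", ncol(raw))
  }
  first <- unlist(raw[1, ], use.names = FALSE)
  looks_header <- identical(tolower(first[1:2]), c("protein_id", "rna_id")) ||
    (ncol(raw) == 3L && !grepl("^[0-9]+$", first[3]))
  if (looks_header) {
    raw <- raw[-1, , drop = FALSE]
    if (nrow(raw) == 0L) stop("pair table has a header but no rows: ", path)
  }
  out <- data.frame(protein_id = raw[[1]], rna_id = raw[[2]],
                    stringsAsFactors = FALSE)
  if (ncol(raw) == 3L) {
    lab <- raw[[3]]
    filled <- nzchar(lab)
    if (any(filled) && !all(filled)) {
      stop("pair table mixes labelled and unlabelled rows")
    }
    if (all(filled)) {
      if (!all(lab %in% c("0", "1"))) {
        stop("labels must be 0 or 1; found: ",
             paste(unique(lab[!lab %in% c("0", "1")]), collapse = ", "))
      }
      out$label <- as.integer(lab)
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a pair table
#'
#' @param pairs `data.frame` with columns `protein_id`, `rna_id` and
#'   optionally `label`.
#' @param path Output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  cols <- intersect(c("protein_id", "rna_id", "label"), names(pairs))
  write.table(pairs[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
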