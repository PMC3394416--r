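#' @importFrom methods as
NULL

# Kyte-Doolittle hydropathy indices for the 20 standard residues.
KD_SCALE <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

STANDARD_AA <- names(KD_SCALE)

#' Construct a protein sequence
#'
#' Residue positions are 1-based throughout the package. Non-standard codes
#' (B, Z, X, U, ...) are accepted with a warning so real-world FASTA input
#' never aborts a screen; their hydropathy defaults to a neutral value.
#'
#' @param id Identifier string.
#' @param residues A single string of one-letter amino-acid codes.
#' @return A list of class \code{"protein_sequence"} with elements
#'   \code{id}, \code{residues} (character vector of single letters) and
#'   \code{N}.
#' @examples
#' protein_sequence("x", "MKV")$N
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  res <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  if (length(res) < 1L) stop("empty sequence for record '", id, "'")
  odd <- setdiff(unique(res), STANDARD_AA)
  if (length(odd) > 0L) {
    warning("sequence '", id, "' contains non-standard residue code(s): ",
            paste(odd, collapse = ", "))
  }
  structure(list(id = id, residues = res, N = length(res)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, x$N))
  invisible(x)
}

#' Kyte-Doolittle hydropathy of residues
#'
#' @param residue Character vector of one-letter codes.
#' @param unknown Value returned for non-standard codes; \code{NULL} to
#'   raise an error instead.
#' @return Numeric vector of hydropathy indices.
#' @examples
#' hydropathy(c("I", "R", "G"))
#' @export
hydropathy <- function(residue, unknown = 0) {
  residue <- toupper(residue)
  out <- unname(KD_SCALE[residue])
  miss <- is.na(out)
  if (any(miss)) {
    if (is.null(unknown)) {
      stop("unknown residue code(s): ",
           paste(unique(residue[miss]), collapse = ", "))
    }
    out[miss] <- unknown
  }
  out
}

seq_string <- function(seq) paste(seq$residues, collapse = "")

#' Read protein sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped lines is supported (parsing is delegated
#' to \pkg{Biostrings}). The header token before the first whitespace
#' becomes the record id.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_sequence()] objects in file order; an empty
#'   list for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1L],
         " should begin a '>' header")
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1L), 1L)
  lapply(seq_along(aa), function(i) {
    protein_sequence(ids[i], as.character(aa[[i]]))
  })
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A list of [protein_sequence()] objects (or a single one).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  strings <- vapply(seqs, seq_string, character(1L))
  aa <- Biostrings::AAStringSet(strings)
  names(aa) <- vapply(seqs, `[[`, character(1L), "id")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Maximal strand runs of a state string
#'
#' @param states Character vector over \code{c("S", "L")}, one per residue.
#' @return Integer matrix with columns \code{start}, \code{end} (1-based
#'   inclusive), one row per maximal run of \code{"S"}.
#' @export
strand_runs <- function(states) {
  r <- rle(states == "S")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Construct a labeled structure
#'
#' Pairs a sequence with per-residue conformation labels over the binary
#' alphabet \code{S} (strand) / \code{L} (turn, loop or anything else) and
#' derives the maximal strand intervals.
#'
#' @param sequence A [protein_sequence()].
#' @param states Character vector (or single string) of labels, same length
#'   as the sequence.
#' @return A list of class \code{"labeled_structure"} with elements
#'   \code{sequence}, \code{states} and \code{strands} (matrix of
#'   start/end).
#' @export
labeled_structure <- function(sequence, states) {
  stopifnot(inherits(sequence, "protein_sequence"))
  if (is.character(states) && length(states) == 1L && sequence$N > 1L) {
    states <- strsplit(states, "", fixed = TRUE)[[1L]]
  }
  if (length(states) != sequence$N) {
    stop("state string length (", length(states),
         ") does not match sequence length (", sequence$N, ") for '",
         sequence$id, "'")
  }
  if (!all(states %in% c("S", "L"))) {
    stop("states must be over the alphabet {S, L}")
  }
  structure(list(sequence = sequence, states = states,
                 strands = strand_runs(states)),
            class = "labeled_structure")
}

#' @export
print.labeled_structure <- function(x, ...) {
  cat(sprintf("<labeled_structure> %s (%d aa, %d strands)\n",
              x$sequence$id, x$sequence$N, nrow(x$strands)))
  invisible(x)
}

#' Read per-residue strand annotations
#'
#' The paired annotation format carries, per record, a FASTA-style header
#' line, one sequence line and one state line over \code{{S, L}} of equal
#' length. This is the carrier for labeled training sets.
#'
#' @param path Path to an annotation file.
#' @return A list of [labeled_structure()] objects in file order.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  if (length(lines) %% 3L != 0L || !startsWith(lines[1L], ">")) {
    stop("annotation format error: expected repeated header/sequence/state ",
         "triples")
  }
  out <- vector("list", length(lines) %/% 3L)
  for (i in seq_along(out)) {
    hdr <- lines[3L * i - 2L]
    if (!startsWith(hdr, ">")) {
      stop("annotation format error: record ", i, " lacks a '>' header")
    }
    id <- strsplit(sub("^>", "", hdr), "\\s+")[[1L]][1L]
    seqline <- trimws(lines[3L * i - 1L])
    stateline <- trimws(lines[3L * i])
    if (nchar(seqline) != nchar(stateline)) {
      stop("annotation format error in record '", id,
           "': sequence and state lines differ in length (",
           nchar(seqline), " vs ", nchar(stateline), ")")
    }
    out[[i]] <- labeled_structure(protein_sequence(id, seqline),
                                  toupper(stateline))
  }
  out
}

#' Write labeled structures as annotation records
#'
#' @param labeled A list of [labeled_structure()] objects (or a single
#'   one).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_annotation <- function(labeled, path) {
  if (inherits(labeled, "labeled_structure")) labeled <- list(labeled)
  con <- file(path, "w")
  on.exit(close(con))
  for (lab in labeled) {
    writeLines(c(paste0(">", lab$sequence$id),
                 seq_string(lab$sequence),
                 paste(lab$states, collapse = "")), con)
  }
  invisible(path)
}
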