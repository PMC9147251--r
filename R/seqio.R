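#' Identified biological sequence
#'
#' Light-weight container for a nucleotide or peptide sequence.  Nucleotide
#' residues are restricted to `A`, `C`, `G`, `T`, `N` after normalization:
#' input is upper-cased and RNA `U` is mapped to `T`, so RNA genomes and DNA
#' genomes are directly comparable.  By default any other IUPAC ambiguity
#' letter is rejected with its position; `lenient = TRUE` maps ambiguity codes
#' to `N` instead.  All coordinates in the package are 1-based and inclusive
#' at both ends.
#'
#' @param residues character scalar of residue letters.
#' @param id sequence label.
#' @param alphabet `"nucleotide"` or `"peptide"`.
#' @param source_note free-text provenance (accession, coordinates, ...).
#' @param lenient map IUPAC ambiguity codes (nucleotide mode) to `N` instead
#'   of rejecting them.
#' @return An object of class `mm_sequence`.
#' @examples
#' s <- mm_sequence("acgu", id = "x")
#' s$residues   # "ACGT"
#' @export
mm_sequence <- function(residues, id = "seq",
                        alphabet = c("nucleotide", "peptide"),
                        source_note = NA_character_, lenient = FALSE) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(residues)
  if (alphabet == "nucleotide") {
    res <- chartr("U", "T", res)
    if (lenient) res <- gsub("[RYSWKMBDHV]", "N", res)
    bad <- regexpr("[^ACGTN]", res)
  } else {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", res)
  }
  if (bad[1] != -1L) {
    stop(sprintf("illegal %s residue '%s' at position %d in sequence '%s'",
                 alphabet, substr(res, bad[1], bad[1]), bad[1], id),
         call. = FALSE)
  }
  if (nchar(res) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  structure(list(id = as.character(id), residues = res, alphabet = alphabet,
                 source_note = source_note),
            class = "mm_sequence")
}

#' @export
length.mm_sequence <- function(x) nchar(x$residues)

#' @export
print.mm_sequence <- function(x, ...) {
  n <- length(x)
  prev <- if (n <= 60) x$residues else paste0(substr(x$residues, 1, 57), "...")
  cat(sprintf("<mm_sequence> %s (%s, %d residues)\n", x$id, x$alphabet, n))
  cat(" ", prev, "\n")
  if (!is.na(x$source_note)) cat("  note:", x$source_note, "\n")
  invisible(x)
}

as_mm_sequence <- function(x, ...) {
  if (inherits(x, "mm_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) return(mm_sequence(x, ...))
  stop("expected an mm_sequence or a character scalar", call. = FALSE)
}

#' Read sequences from a FASTA file
#'
#' One `mm_sequence` per record, in file order, with the full header line kept
#' as the id.  Residues are normalized as in [mm_sequence()] (upper case,
#' `U -> T` in nucleotide mode).
#'
#' @param path FASTA file.
#' @param alphabet,lenient passed to [mm_sequence()].
#' @return A list of `mm_sequence`.
#' @export
read_fasta <- function(path, alphabet = "nucleotide", lenient = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop(sprintf("cannot parse FASTA file %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L)
    stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- mm_sequence(as.character(set[[i]]), id = names(set)[i],
                            alphabet = alphabet,
                            source_note = sprintf("%s record %d", basename(path), i),
                            lenient = lenient)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 60 columns.
#'
#' @param seqs an `mm_sequence` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "mm_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(setNames(
    vapply(seqs, function(s) s$residues, character(1)),
    vapply(seqs, function(s) s$id, character(1))))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta", width = 60L)
  invisible(path)
}

#' Extract a subsequence by 1-based inclusive coordinates
#'
#' @param seq an `mm_sequence`.
#' @param start,end 1-based positions, both included; the result has length
#'   `end - start + 1`.
#' @return An `mm_sequence` whose `source_note` records the interval.
#' @export
subsequence <- function(seq, start, end) {
  seq <- as_mm_sequence(seq)
  n <- length(seq)
  if (start < 1 || end > n || start > end)
    stop(sprintf("invalid interval [%d, %d] for sequence of length %d",
                 start, end, n), call. = FALSE)
  structure(list(id = seq$id,
                 residues = substr(seq$residues, start, end),
                 alphabet = seq$alphabet,
                 source_note = sprintf("%s:%d-%d", seq$id, start, end)),
            class = "mm_sequence")
}

#' Reverse complement of a nucleotide sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.  Applying the function
#' twice returns the input.
#'
#' @param seq an `mm_sequence` (nucleotide).
#' @return An `mm_sequence`.
#' @export
reverse_complement <- function(seq) {
  seq <- as_mm_sequence(seq)
  if (seq$alphabet != "nucleotide")
    stop("reverse_complement requires a nucleotide sequence", call. = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq$residues)))
  structure(list(id = seq$id, residues = rc, alphabet = seq$alphabet,
                 source_note = paste0("revcomp(",
                                      seq$source_note %||% seq$id, ")")),
            class = "mm_sequence")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Exact letter composition of a nucleotide sequence
#'
#' @param seq an `mm_sequence` (nucleotide).
#' @return An `mm_composition`: named counts over `A, C, G, T` (and `N` when
#'   present) summing to the sequence length.
#' @export
composition <- function(seq) {
  seq <- as_mm_sequence(seq)
  if (seq$alphabet != "nucleotide")
    stop("composition requires a nucleotide sequence", call. = FALSE)
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq$residues))
  counts <- f[c("A", "C", "G", "T")]
  if (f[["N"]] > 0) counts <- c(counts, N = f[["N"]])
  new_composition(counts)
}

new_composition <- function(counts) {
  counts <- as.integer(counts) |> setNames(names(counts))
  if (any(counts < 0)) stop("negative composition counts", call. = FALSE)
  structure(list(counts = counts, length = sum(counts)),
            class = "mm_composition")
}

#' Composition profile from explicit counts
#'
#' @param ... named letter counts, e.g. `composition_profile(A = 2, C = 1, G = 1)`.
#' @return An `mm_composition`.
#' @export
composition_profile <- function(...) {
  counts <- c(...)
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("composition counts must be named by letter", call. = FALSE)
  new_composition(counts)
}

#' @export
print.mm_composition <- function(x, ...) {
  cat("<mm_composition> length", x$length, "\n")
  print(x$counts)
  invisible(x)
}

#' Published base composition of the Wuhan reference genome
#'
#' Letter counts of the 29,903-nt Wuhan-Hu-1 SARS-CoV-2 reference record
#' (U counted as T).  Used as the template for composition-matched
#' randomization; the package's control analyses build *synthetic*
#' exact-composition stand-ins from this profile rather than shipping the
#' genome record itself.
#'
#' @return An `mm_composition` of length 29,903.
#' @export
sarscov2_composition <- function() {
  composition_profile(A = 8954L, C = 5492L, G = 5863L, T = 9594L)
}
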