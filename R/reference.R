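#' Create a reference set
#'
#' A reference set holds the named nucleotide sequences (the color universe)
#' that an index is built over. Sequence order is stable and defines the
#' 0-based reference ids used everywhere else in the package.
#'
#' @param seqs named character vector (or named list) of nucleotide
#'   sequences over A, C, G, T, N. Lower case is accepted and upper-cased.
#' @return an object of class `reference_set` with fields `names`, `seqs`
#'   and `L` (sequence lengths in bases).
#' @examples
#' rs <- reference_set(c(chr1 = "ACGTACGTAA", chr2 = "TTTTACGT"))
#' rs$L
#' @export
reference_set <- function(seqs) {
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("empty reference set")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("references must be named")
  if (anyDuplicated(nm)) stop("reference names must be unique")
  seqs <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("reference sequences may only contain A, C, G, T, N (offending: ",
                     nm[bad][1L], ")")
  structure(list(names = nm, seqs = unname(seqs), L = unname(nchar(seqs))),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d sequence(s), %s bases total\n",
              length(x$names), format(sum(as.numeric(x$L)), big.mark = ",")))
  invisible(x)
}

as_reference_set <- function(x) {
  if (inherits(x, "reference_set")) return(x)
  if (is.character(x)) return(reference_set(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a reference set")
}

#' Read references from a FASTA file
#'
#' @param path path to a (optionally gzipped) multi-record FASTA file.
#' @return a [reference_set()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  reference_set(stats::setNames(as.character(ss), nm))
}

#' Write a reference set to FASTA
#'
#' @param refs a [reference_set()].
#' @param path output path; gzipped when it ends in `.gz`.
#' @export
write_fasta <- function(refs, path) {
  refs <- as_reference_set(refs)
  ss <- Biostrings::DNAStringSet(stats::setNames(refs$seqs, refs$names))
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
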