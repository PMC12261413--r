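#' Build a compacted de Bruijn graph index over a reference set
#'
#' Constructs the two maps that together resolve a k-mer to its genomic
#' positions: K->U, from each distinct canonical k-mer to a
#' (unitig, offset, orientation) triplet, and U->R, from each unitig to the
#' list of its oriented occurrences on the references. Canonical form is the
#' lexicographic minimum of a k-mer and its reverse complement; k must be
#' odd so no k-mer is its own reverse complement. References are split into
#' contigs at non-ACGT characters before k-mer extraction, and unitigs are
#' maximal non-branching paths additionally split wherever a contig starts
#' or ends mid-path, so that each reference is tiled exactly by complete
#' oriented unitig occurrences over its non-N stretches.
#'
#' @param refs a [reference_set()], or a named character vector of sequences.
#' @param k odd k-mer length, 15..31 (default 25). Values below 15 are
#'   rejected unless `allow_small_k = TRUE` (they are accepted with a
#'   warning; useful for toy examples only).
#' @param allow_small_k override the k >= 15 requirement.
#' @return an object of class `dbg_index`: k, reference names/lengths, the
#'   unitig set, the sorted canonical k-mer table and the per-unitig
#'   occurrence lists. Unitig ids are 1-based; reference ids are 0-based;
#'   offsets and positions are 0-based.
#' @examples
#' idx <- build_index(c(r1 = "ACGTTGCAACGT"), k = 5, allow_small_k = TRUE)
#' idx
#' @seealso [lookup_kmer()], [kmer_positions()], [save_index()]
#' @export
build_index <- function(refs, k = 25L, allow_small_k = FALSE) {
  refs <- as_reference_set(refs)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be a positive integer")
  if (k %% 2L == 0L)
    stop("k must be odd: an even k admits k-mers equal to their own ",
         "reverse complement, making canonical orientation ambiguous")
  if (k > 31L) stop("k must be <= 31")
  if (k < 15L) {
    if (!allow_small_k)
      stop("k < 15 is rejected (set allow_small_k = TRUE to override)")
    warning("k < 15: expect dense k-mer collisions; intended for toy data only")
  }
  idx <- .build_index_cpp(refs$seqs, k)
  idx$ref_names <- refs$names
  idx$ref_len <- as.integer(refs$L)
  class(idx) <- "dbg_index"
  idx
}

#' @export
print.dbg_index <- function(x, ...) {
  cat(sprintf(paste0("dbg_index: k=%d, %d reference(s) (%s bases), ",
                     "%s unitigs, %s canonical k-mers\n"),
              x$k, length(x$ref_names),
              format(sum(as.numeric(x$ref_len)), big.mark = ","),
              format(length(x$unitigs), big.mark = ","),
              format(length(x$kmer_hi), big.mark = ",")))
  invisible(x)
}

#' Look up k-mers in the index (K->U)
#'
#' Resolves each queried k-mer to its unitig, 0-based offset within the
#' unitig, and orientation *relative to the queried string* ("f" when the
#' k-mer as written matches the unitig forward strand). A k-mer and its
#' reverse complement resolve to the same (unitig, offset) with flipped
#' orientation. Absent k-mers, non-ACGT queries and wrong-length queries
#' return no hit, never an error.
#'
#' @param index a [build_index()] result.
#' @param kmers character vector of query k-mers.
#' @return a `data.table` with one row per query: `kmer`, `present`,
#'   `unitig` (1-based id or NA), `off`, `ori` ("f"/"r" or NA).
#' @export
lookup_kmer <- function(index, kmers) {
  stopifnot(inherits(index, "dbg_index"))
  r <- .lookup_kmer_cpp(unclass(index), as.character(kmers))
  data.table(kmer = as.character(kmers), present = r$present,
             unitig = r$uid, off = r$off,
             ori = ifelse(is.na(r$fwd), NA_character_,
                          c("r", "f")[r$fwd + 1L]))
}

#' Genomic positions of a k-mer
#'
#' Composes K->U with U->R: returns every occurrence of the k-mer on the
#' references as 0-based start positions on the forward strand, with the
#' orientation of the *queried* k-mer relative to the reference. The result
#' is sorted by (reference id, position); an absent k-mer yields zero rows.
#'
#' @param index a [build_index()] result.
#' @param kmer a single k-mer string.
#' @return a `data.table` with columns `ref` (0-based reference id),
#'   `ref_name`, `pos` and `ori`.
#' @export
kmer_positions <- function(index, kmer) {
  stopifnot(inherits(index, "dbg_index"), length(kmer) == 1L)
  r <- .kmer_positions_cpp(unclass(index), as.character(kmer))
  data.table(ref = r$ref, ref_name = index$ref_names[r$ref + 1L],
             pos = r$pos, ori = c("r", "f")[r$fwd + 1L])
}

# ---- serialization ---------------------------------------------------------
# Container layout (little-endian, versioned):
#   bytes 0..7   magic "VCATACIX"
#   int32        format version (1)
#   int32        k, n_refs, n_unitigs, n_kmers, n_occ
#   per ref      int32 name length, raw name bytes, int32 ref length
#   int32[n_unitigs]   unitig lengths, then concatenated unitig bytes
#   int32 arrays kmer_hi, kmer_lo, kmer_uid, kmer_off, kmer_fwd
#   int32 arrays occ_ptr (n_unitigs+1), occ_ref, occ_pos, occ_fwd

.vcx_magic <- charToRaw("VCATACIX")

#' Save / load a de Bruijn graph index
#'
#' Serializes the index to a versioned binary container (magic, k, counts,
#' unitig sequences, the K->U table and the U->R occurrence lists).
#' `load_index(save_index(idx, f))` is bit-exact: the loaded object is
#' `identical()` to the one saved.
#'
#' @param index a [build_index()] result.
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   `dbg_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "dbg_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(.vcx_magic, con)
  wi(1L)
  wi(c(index$k, length(index$ref_names), length(index$unitigs),
       length(index$kmer_hi), length(index$occ_ref)))
  for (i in seq_along(index$ref_names)) {
    nm <- charToRaw(index$ref_names[i])
    wi(length(nm)); writeBin(nm, con); wi(index$ref_len[i])
  }
  wi(index$unitig_len)
  writeBin(charToRaw(paste(index$unitigs, collapse = "")), con)
  for (f in c("kmer_hi", "kmer_lo", "kmer_uid", "kmer_off", "kmer_fwd",
              "occ_ptr", "occ_ref", "occ_pos", "occ_fwd"))
    wi(index[[f]])
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, .vcx_magic)) stop("not a vcatac index file: ", path)
  ver <- ri(1L)
  if (ver != 1L) stop("unsupported index format version ", ver)
  hdr <- ri(5L)
  k <- hdr[1L]; n_refs <- hdr[2L]; n_u <- hdr[3L]; n_k <- hdr[4L]; n_o <- hdr[5L]
  ref_names <- character(n_refs); ref_len <- integer(n_refs)
  for (i in seq_len(n_refs)) {
    nl <- ri(1L)
    ref_names[i] <- rawToChar(readBin(con, "raw", n = nl))
    ref_len[i] <- ri(1L)
  }
  ulen <- ri(n_u)
  ucat <- rawToChar(readBin(con, "raw", n = sum(as.numeric(ulen))))
  ends <- cumsum(ulen)
  unitigs <- substring(ucat, ends - ulen + 1L, ends)
  idx <- list(k = k, unitigs = unitigs, unitig_len = ulen,
              kmer_hi = ri(n_k), kmer_lo = ri(n_k), kmer_uid = ri(n_k),
              kmer_off = ri(n_k), kmer_fwd = ri(n_k),
              occ_ptr = ri(n_u + 1L), occ_ref = ri(n_o), occ_pos = ri(n_o),
              occ_fwd = ri(n_o),
              ref_names = ref_names, ref_len = ref_len)
  class(idx) <- "dbg_index"
  idx
}
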