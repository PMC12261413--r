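#' Read a cell-barcode permit list
#'
#' One barcode per line, all the same length, over A, C, G, T; gzipped
#' files are accepted.
#'
#' @param path permit list file.
#' @return character vector of class `permit_list`.
#' @export
read_permit_list <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  bc <- readLines(con)
  bc <- bc[nzchar(bc)]
  permit_list(bc)
}

#' @rdname read_permit_list
#' @param barcodes character vector of barcodes.
#' @export
permit_list <- function(barcodes) {
  barcodes <- toupper(as.character(barcodes))
  if (length(barcodes) == 0L) stop("permit list is empty")
  if (length(unique(nchar(barcodes))) != 1L)
    stop("permit list barcodes must all have the same length")
  if (any(grepl("[^ACGT]", barcodes)))
    stop("permit list barcodes must be over A, C, G, T")
  structure(unique(barcodes), class = "permit_list")
}

#' Correct observed barcodes against a permit list
#'
#' An observed barcode already in the permit list is kept as is. Otherwise
#' its nearest neighbors at Hamming distance 1 are sought: a unique
#' neighbor corrects the barcode; zero or several neighbors drop it under
#' the default `"unique"` policy. The `"frequency"` policy instead breaks
#' multi-candidate ties in favor of the candidate with the highest exact
#' match count observed in the run (remaining ties are dropped). Barcodes
#' whose length differs from the permit barcodes are dropped.
#'
#' @param bc character vector of observed barcodes.
#' @param permit a [permit_list()].
#' @param policy `"unique"` (default) or `"frequency"`.
#' @param exact_counts named integer vector of exact-match counts per
#'   permit barcode (only used by the frequency policy); computed from
#'   `bc` itself when omitted.
#' @return character vector parallel to `bc`; `NA` marks dropped barcodes.
#' @export
correct_barcode <- function(bc, permit, policy = c("unique", "frequency"),
                            exact_counts = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(permit, "permit_list"))
  bc <- as.character(bc)
  blen <- nchar(permit[1L])
  out <- rep(NA_character_, length(bc))
  ok_len <- !is.na(bc) & nchar(bc) == blen
  hit <- ok_len & bc %in% permit
  out[hit] <- bc[hit]
  todo <- which(ok_len & !hit)
  if (length(todo) == 0L) return(out)

  if (policy == "frequency" && is.null(exact_counts)) {
    tb <- table(bc[hit])
    exact_counts <- stats::setNames(as.integer(tb), names(tb))
  }
  uq <- unique(bc[todo])
  # all Hamming-1 neighbors of each unmatched barcode, checked against the set
  pset <- as.character(permit)
  corrected <- vapply(uq, function(b) {
    cand <- character(0)
    for (p in seq_len(blen)) {
      orig <- substr(b, p, p)
      for (base in c("A", "C", "G", "T")) {
        if (base == orig) next
        nb <- b
        substr(nb, p, p) <- base
        if (nb %in% pset) cand <- c(cand, nb)
      }
    }
    cand <- unique(cand)
    if (length(cand) == 1L) return(cand)
    if (length(cand) >= 2L && policy == "frequency") {
      cnt <- exact_counts[cand]
      cnt[is.na(cnt)] <- 0L
      best <- cand[cnt == max(cnt)]
      if (length(best) == 1L) return(best)
    }
    NA_character_
  }, character(1))
  out[todo] <- corrected[match(bc[todo], uq)]
  out
}

#' Barcode-correct a fragment table
#'
#' Applies [correct_barcode()] to the `barcode` column, drops fragments
#' whose barcode cannot be corrected, and reports conservation counts
#' (`n_in = n_kept + n_dropped`).
#'
#' @param fragments `data.table` with at least a `barcode` column.
#' @param permit a [permit_list()].
#' @param policy see [correct_barcode()].
#' @return list with `fragments` (corrected, dropped rows removed) and
#'   `stats` (`n_in`, `n_exact`, `n_rescued`, `n_dropped`).
#' @export
correct_barcodes <- function(fragments, permit, policy = "unique") {
  fragments <- as.data.table(fragments)
  corrected <- correct_barcode(fragments$barcode, permit, policy)
  n_exact <- sum(!is.na(fragments$barcode) &
                   fragments$barcode %in% as.character(permit))
  keep <- !is.na(corrected)
  out <- fragments[keep]
  out[, barcode := corrected[keep]]
  list(fragments = out,
       stats = list(n_in = nrow(fragments), n_exact = n_exact,
                    n_rescued = sum(keep) - n_exact,
                    n_dropped = sum(!keep)))
}

# sortable key string: fixed-width digits + barcode letters, so that plain
# string order equals the (ref_id, start, end, barcode, input row) tuple order
.frag_key <- function(dt, row0) {
  sprintf("%08d%012d%012d%s%010d",
          dt$ref_id, dt$start, dt$end, dt$barcode, row0)
}

.frag_check <- function(records) {
  records <- as.data.table(records)
  need <- c("ref_id", "start", "end", "barcode")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("fragment records lack column(s): ", paste(miss, collapse = ", "))
  records
}

#' Sort fragment records by genomic coordinate
#'
#' Total order: reference id (FASTA appearance order), start, end, barcode
#' (C locale). When the input exceeds `chunk_size` rows, sorted runs are
#' spilled to temporary files and k-way merged; the result is identical --
#' including tie order -- to a single in-memory sort for any chunk size.
#'
#' @param records fragment `data.table` with columns `ref_id`, `start`,
#'   `end`, `barcode` (extra columns are carried along).
#' @param chunk_size rows held in memory at once (default: all).
#' @return the sorted `data.table`.
#' @export
sort_fragments <- function(records, chunk_size = Inf) {
  records <- .frag_check(records)
  if (nrow(records) == 0L) return(records)
  if (chunk_size < 1) stop("chunk_size must be >= 1")
  if (nrow(records) <= chunk_size) {
    out <- copy(records)
    setorder(out, ref_id, start, end, barcode)
    return(out)
  }
  # external path: spill sorted key runs, then k-way merge; the merged key
  # sequence is the permutation applied to the in-memory records, so no
  # value ever round-trips through text
  n <- nrow(records)
  row0 <- seq_len(n)
  keys <- .frag_key(records, row0)
  starts <- seq.int(1L, n, by = as.integer(chunk_size))
  run_files <- character(length(starts))
  for (i in seq_along(starts)) {
    sel <- starts[i]:min(starts[i] + chunk_size - 1L, n)
    run <- data.table(key0 = keys[sel], .row0 = row0[sel])
    setorder(run, key0)
    run_files[i] <- tempfile(fileext = ".run.tsv")
    fwrite(run, run_files[i], sep = "\t", quote = FALSE)
  }
  on.exit(unlink(run_files))
  bufs <- lapply(run_files, fread, sep = "\t",
                 colClasses = list(character = "key0"))
  ptr <- rep(1L, length(bufs))
  nrows <- vapply(bufs, nrow, integer(1))
  ord <- integer(n)
  for (t in seq_len(n)) {
    best <- 0L
    bkey <- ""
    for (j in seq_along(bufs)) {
      if (ptr[j] > nrows[j]) next
      kj <- bufs[[j]]$key0[ptr[j]]
      if (best == 0L || kj < bkey) { best <- j; bkey <- kj }
    }
    ord[t] <- bufs[[best]]$.row0[ptr[best]]
    ptr[best] <- ptr[best] + 1L
  }
  records[ord]
}

#' Collapse duplicate fragments into BED records
#'
#' Consecutive records equal on (reference, start, end, barcode) collapse
#' into one record whose count is the group size (the total number of
#' duplicates including the fragment itself); counts therefore sum to the
#' number of input records. The input must already be sorted as by
#' [sort_fragments()]; unsorted input is rejected.
#'
#' @param sorted sorted fragment `data.table` (needs `ref_id`, `start`,
#'   `end`, `barcode`; a `ref` name column is carried into the output when
#'   present).
#' @return `data.table` of BED records: `chrom`, `start`, `end`,
#'   `barcode`, `count`.
#' @export
dedup_fragments <- function(sorted) {
  sorted <- .frag_check(sorted)
  if (nrow(sorted) == 0L)
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), barcode = character(0),
                      count = integer(0)))
  chk <- sorted[, .(ref_id, start, end, barcode)]
  srt <- copy(chk)
  setorder(srt, ref_id, start, end, barcode)
  if (!isTRUE(all.equal(chk, srt, check.attributes = FALSE)))
    stop("dedup_fragments() requires input sorted by ",
         "(reference, start, end, barcode); run sort_fragments() first")
  chrom <- if ("ref" %in% names(sorted)) sorted$ref else
    as.character(sorted$ref_id)
  out <- data.table(chrom = chrom, start = sorted$start, end = sorted$end,
                    barcode = sorted$barcode)
  out <- out[, .(count = .N), by = .(chrom, start, end, barcode)]
  out[]
}

#' Write / read a fragment BED file
#'
#' Five tab-separated columns -- reference name, start, end, cell barcode,
#' duplicate count -- with 0-based half-open intervals, the standard
#' scATAC-seq fragment-file format consumed by peak callers. Reading
#' validates every line and reports the first malformed line number.
#'
#' @param bed a [dedup_fragments()] result.
#' @param path output path; gzipped when ending in `.gz`.
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end", "barcode", "count") %in% names(bed)))
  fwrite(bed[, .(chrom, start, end, barcode, count)], path, sep = "\t",
         col.names = FALSE, quote = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

# fread with transparent gzip support (no external helpers needed)
.fread_gz <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    fread(text = readLines(con), ...)
  } else {
    fread(path, ...)
  }
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- .fread_gz(path, sep = "\t", header = FALSE,
                 colClasses = list(character = c(1L, 4L)))
  if (ncol(x) != 5L)
    stop("malformed BED: expected 5 columns, found ", ncol(x))
  setnames(x, c("chrom", "start", "end", "barcode", "count"))
  for (col in c("start", "end", "count")) {
    v <- suppressWarnings(as.integer(x[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed BED line ", bad[1L], ": non-integer ", col)
    x[[col]] <- v
  }
  bad <- which(x$start < 0L | x$end <= x$start | x$count < 1L)
  if (length(bad))
    stop("malformed BED line ", bad[1L],
         ": requires 0 <= start < end and count >= 1")
  x[]
}

#' Run the full fragment-processing stage
#'
#' Barcode correction against the permit list, coordinate sorting
#' (optionally external-memory), duplicate collapsing, and BED emission.
#' Optionally applies the Tn5 +4/-5 coordinate shift before sorting
#' (off by default).
#'
#' @param fragments fragment `data.table` (e.g. `map_pairs()$fragments`)
#'   or path to a TSV written by [write_fragments()].
#' @param permit a [permit_list()] or path to one.
#' @param out_bed optional BED output path.
#' @param chunk_size see [sort_fragments()].
#' @param policy see [correct_barcode()].
#' @param tn5_shift apply the +4/-5 Tn5 dyad shift to fragment
#'   coordinates.
#' @return list with `bed` and `stats` (barcode-correction conservation
#'   counts plus `n_bed_records` and `sum_counts`).
#' @export
process_fragments <- function(fragments, permit, out_bed = NULL,
                              chunk_size = Inf, policy = "unique",
                              tn5_shift = FALSE) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  if (!inherits(permit, "permit_list"))
    permit <- read_permit_list(permit)
  fragments <- .frag_check(fragments)
  corr <- correct_barcodes(fragments, permit, policy)
  fr <- corr$fragments
  if (tn5_shift && nrow(fr)) {
    fr <- copy(fr)
    fr[, `:=`(start = start + 4L, end = end - 5L)]
    fr <- fr[start < end]
  }
  sorted <- sort_fragments(fr, chunk_size = chunk_size)
  bed <- dedup_fragments(sorted)
  stats <- c(corr$stats,
             list(n_shifted_out = corr$stats$n_in - corr$stats$n_dropped -
                    nrow(fr),
                  n_bed_records = nrow(bed),
                  sum_counts = sum(bed$count)))
  if (!is.null(out_bed)) write_bed(bed, out_bed)
  list(bed = bed, stats = stats)
}

#' Write / read the mapper's intermediate fragment stream
#'
#' A documented TSV standing in for a compact binary intermediate: columns
#' `read_id`, `barcode`, `ref_id` (0-based, FASTA order), `ref`, `start`,
#' `end`, `ori` (orientation of mate 1) and `frac` (combined support
#' fraction).
#'
#' @param fragments `map_pairs()$fragments`.
#' @param path TSV path (gzipped when ending in `.gz`).
#' @export
write_fragments <- function(fragments, path) {
  cols <- c("read_id", "barcode", "ref_id", "ref", "start", "end", "ori",
            "frac")
  stopifnot(all(cols %in% names(fragments)))
  fwrite(as.data.table(fragments)[, ..cols], path, sep = "\t",
         quote = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  .fread_gz(path, sep = "\t", colClasses = list(
    character = c("read_id", "barcode", "ref", "ori")))
}
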