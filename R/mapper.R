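#' Mapping parameters
#'
#' Bundles the tunable parameters of the paired-end virtual-color mapper.
#' Defaults are the best-performing setting observed for scATAC-seq-scale
#' reads: `k = 25`, `tau = 0.7`, `lvcol = 1000`, with mate-merge constraints
#' `dovetail_max = 20` and `ins_max = 1000`.
#'
#' @param tau pseudoalignment threshold in (0, 1]: a virtual color must be
#'   supported by at least `tau * |K(Q)|` of the read's index-matched
#'   k-mers.
#' @param k k-mer length the index is expected to use.
#' @param lvcol virtual-color bin stride in bases.
#' @param ov_length bin overlap in bases; `NULL` (default) chooses
#'   `max(150, 2 * max observed read length)` at map time, which satisfies
#'   the requirement that the overlap be at least the read length.
#' @param dovetail_max largest tolerated dovetail (reverse mate starting
#'   before the forward mate), in bases.
#' @param ins_max largest tolerated distance between mate start positions,
#'   in bases.
#' @param cache_capacity maximum number of entries in the terminal k-mer
#'   cache (default 5,000,000).
#' @param streaming use unitig-extension streaming queries (results are
#'   identical either way; this only changes lookup cost).
#' @param use_cache use the write-once terminal k-mer cache (streaming mode
#'   only; results are identical either way).
#' @param premerge_mates optionally merge overlapping mates into a unified
#'   fragment before mapping (see [merge_overlapping_mates()]); off by
#'   default.
#' @return an object of class `map_params`.
#' @export
map_params <- function(tau = 0.7, k = 25L, lvcol = 1000L, ov_length = NULL,
                       dovetail_max = 20L, ins_max = 1000L,
                       cache_capacity = 5e6, streaming = TRUE,
                       use_cache = TRUE, premerge_mates = FALSE) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
    stop("tau must lie in (0, 1]")
  structure(list(tau = tau, k = as.integer(k), lvcol = as.integer(lvcol),
                 ov_length = if (!is.null(ov_length)) as.integer(ov_length),
                 dovetail_max = as.integer(dovetail_max),
                 ins_max = as.integer(ins_max),
                 cache_capacity = cache_capacity,
                 streaming = isTRUE(streaming), use_cache = isTRUE(use_cache),
                 premerge_mates = isTRUE(premerge_mates)),
            class = "map_params")
}

# ---- terminal k-mer cache --------------------------------------------------

#' Write-once terminal k-mer cache
#'
#' A fixed-capacity map from terminal canonical k-mers (the first or last
#' k-mer of a unitig with respect to traversal) to their index entries.
#' Entries are written once and never replaced; once the capacity is
#' reached no further entries are added. The cache changes only lookup
#' cost, never mapping output. It may be shared across [map_pairs()] calls.
#'
#' @param capacity maximum number of entries (default 5,000,000).
#' @return an object of class `kmer_cache`.
#' @export
new_kmer_cache <- function(capacity = 5e6) {
  structure(list(ptr = .new_kmer_cache_cpp(as.numeric(capacity))),
            class = "kmer_cache")
}

#' @rdname new_kmer_cache
#' @param cache a `kmer_cache`.
#' @export
cache_size <- function(cache) {
  stopifnot(inherits(cache, "kmer_cache"))
  .kmer_cache_size_cpp(cache$ptr)
}

#' @rdname new_kmer_cache
#' @export
cache_capacity <- function(cache) {
  stopifnot(inherits(cache, "kmer_cache"))
  .kmer_cache_capacity_cpp(cache$ptr)
}

#' @rdname new_kmer_cache
#' @param k k-mer length used to decode cached keys.
#' @export
cache_entries <- function(cache, k) {
  stopifnot(inherits(cache, "kmer_cache"))
  as.data.table(.kmer_cache_entries_cpp(cache$ptr, as.integer(k)))
}

.cache_ptr <- function(cache) if (is.null(cache)) NULL else cache$ptr

# ---- k-mer query and per-mate pseudoalignment ------------------------------

#' Streaming k-mer query over a read
#'
#' Returns one slot per read k-mer, identical to independent
#' [lookup_kmer()] calls: streaming extension and the terminal k-mer cache
#' are pure optimizations. When the previous k-mer's unitig has not been
#' exhausted, the next reference nucleotide is extracted from the unitig
#' and compared against the new k-mer's last nucleotide; on a match the
#' entry is produced without touching the index. Terminal k-mers (the
#' previous k-mer sat at the unitig end) consult and, on a successful miss
#' with spare capacity, populate the cache. Non-ACGT k-mers yield empty
#' slots and reset the state.
#'
#' @param index a [build_index()] result.
#' @param read a read sequence.
#' @param cache optional [new_kmer_cache()].
#' @param streaming disable to force a full index query per k-mer.
#' @return `data.table` with one row per k-mer (`present`, `unitig`, `off`,
#'   `ori`); attribute `n_queries` counts full index queries made.
#' @export
query_kmers_streaming <- function(index, read, cache = NULL, streaming = TRUE) {
  stopifnot(inherits(index, "dbg_index"), length(read) == 1L)
  r <- .query_kmers_streaming_cpp(unclass(index), as.character(read),
                                  isTRUE(streaming), .cache_ptr(cache))
  out <- data.table(present = r$present, unitig = r$uid, off = r$off,
                    ori = ifelse(is.na(r$fwd), NA_character_,
                                 c("r", "f")[r$fwd + 1L]))
  setattr(out, "n_queries", r$n_queries)
  out
}

.hits_dt <- function(r) {
  data.table(ref = r$ref, pos = r$pos,
             ori = c("r", "f")[r$fwd + 1L],
             vid = r$vid, support = r$support,
             kq = rep(r$kq, length(r$ref)))
}

.hits_args <- function(hits) {
  list(ref = as.integer(hits$ref), pos = as.integer(hits$pos),
       fwd = hits$ori == "f", vid = as.integer(hits$vid),
       support = as.integer(hits$support))
}

#' Pseudoalign one mate against virtual colors
#'
#' Threshold-union pseudoalignment of a single read. `K(Q)` is the set of
#' read k-mers with an index entry; every occurrence of each such k-mer is
#' expanded to its virtual color id(s), support is tallied per
#' (virtual color, read orientation) counting each read k-mer at most once
#' per pair, and a hit is emitted for every pair supported by at least
#' `tau * |K(Q)|` k-mers. The reported position is the inferred 0-based
#' read start on the reference forward strand, anchored on the
#' leftmost-in-read supporting k-mer (taking the smallest reference
#' coordinate within the bin when that k-mer occurs several times) and
#' clamped at 0. Reads with `K(Q)` empty, or shorter than k, are unmapped
#' (zero rows).
#'
#' @param index a [build_index()] result.
#' @param scheme a [build_scheme()] result over the same references.
#' @param read a read sequence.
#' @param tau threshold in (0, 1].
#' @param streaming,cache see [query_kmers_streaming()].
#' @return `data.table` of hits: `ref` (0-based), `pos`, `ori`, `vid`,
#'   `support`, `kq` (= |K(Q)|).
#' @export
pseudoalign_mate <- function(index, scheme, read, tau = 0.7, streaming = TRUE,
                             cache = NULL) {
  stopifnot(inherits(index, "dbg_index"), inherits(scheme, "vcolor_scheme"),
            length(read) == 1L)
  r <- .pseudoalign_mate_cpp(unclass(index), as.character(read), scheme$CB,
                             scheme$B, scheme$lvcol, scheme$ov_length, tau,
                             isTRUE(streaming), .cache_ptr(cache))
  .hits_dt(r)
}

#' Remove duplicate hits induced by bin overlap
#'
#' A k-mer (hence a read) in an overlap region is assigned two virtual
#' colors for the same reference position, so a mate can carry two hits
#' equal on (orientation, reference, position) that differ only in virtual
#' color id. Among such duplicates only the hit with the smaller id is
#' kept. By construction a duplicate group has size at most 2; a larger
#' group indicates an internal invariant violation and raises an error.
#'
#' @param hits a [pseudoalign_mate()] result.
#' @return the deduplicated hits, ordered by (ori, ref, pos).
#' @export
dedup_hits <- function(hits) {
  a <- .hits_args(hits)
  r <- .dedup_hits_cpp(a$ref, a$pos, a$fwd, a$vid, a$support)
  if (r$max_group > 2L)
    stop("internal invariant violation: duplicate hit group of size ",
         r$max_group, " (expected at most 2)")
  kq <- if (nrow(hits)) hits$kq[1L] else integer(0)
  data.table(ref = r$ref, pos = r$pos, ori = c("r", "f")[r$fwd + 1L],
             vid = r$vid, support = r$support,
             kq = rep(if (length(kq)) kq else NA_integer_, length(r$ref)))
}

#' Merge deduplicated mate hits into candidate fragment mappings
#'
#' A hit `a` of mate 1 and a hit `b` of mate 2 merge when they lie on the
#' same reference in adjacent or equal virtual colors
#' (`|vid(a) - vid(b)| <= 1`), have opposite orientations, and their
#' positions are compatible: `-dovetail_max <= pos(b) - pos(a) <= ins_max`
#' when mate 1 maps forward (roles swapped when it maps reverse). The
#' merged fragment spans `[min(pos), max(pos) + read length of the
#' downstream mate)` and carries the combined support fraction
#' `(support1 + support2) / (kq1 + kq2)`.
#'
#' @param hits1,hits2 deduplicated hits of mate 1 and mate 2.
#' @param rl1,rl2 mate read lengths in bases.
#' @param dovetail_max,ins_max merge constraints in bases.
#' @return `data.table` of merged mappings: `ref`, `start`, `end`, `ori1`
#'   (orientation of mate 1), `frac`.
#' @export
merge_mates <- function(hits1, hits2, rl1, rl2, dovetail_max = 20L,
                        ins_max = 1000L) {
  a1 <- .hits_args(hits1); a2 <- .hits_args(hits2)
  kq1 <- if (nrow(hits1)) hits1$kq[1L] else 0L
  kq2 <- if (nrow(hits2)) hits2$kq[1L] else 0L
  r <- .merge_mates_cpp(a1$ref, a1$pos, a1$fwd, a1$vid, a1$support,
                        as.integer(kq1), as.integer(rl1),
                        a2$ref, a2$pos, a2$fwd, a2$vid, a2$support,
                        as.integer(kq2), as.integer(rl2),
                        as.integer(dovetail_max), as.integer(ins_max))
  data.table(ref = r$ref, start = r$start, end = r$end,
             ori1 = c("r", "f")[r$fwd1 + 1L], frac = r$frac)
}

#' Keep only best-supported merged mappings
#'
#' With `tau < 1`, surviving merged mappings can be supported by different
#' numbers of k-mers. Let tau' be the largest combined support fraction
#' over the candidate list; all mappings with a smaller fraction are
#' filtered out (ties all survive, and a read pair with several survivors
#' is discarded downstream as multimapping).
#'
#' @param merged a [merge_mates()] result.
#' @return the filtered `data.table` (empty input gives empty output).
#' @export
filter_best_support <- function(merged) {
  if (nrow(merged) == 0L) return(merged)
  merged[frac >= max(frac) - 1e-9]
}

# ---- paired-end orchestration ----------------------------------------------

#' Map one read pair
#'
#' Runs [pseudoalign_mate()] for each mate, [dedup_hits()],
#' [merge_mates()] and [filter_best_support()], and emits a fragment
#' record only when exactly one merged mapping survives; otherwise the
#' pair is reported unmapped (no candidate) or multimapped (several tied
#' candidates).
#'
#' @param index a [build_index()] result.
#' @param r1,r3 the two genomic mate sequences.
#' @param barcode the (uncorrected) cell barcode carried by the pair.
#' @param params a [map_params()].
#' @param scheme optional [build_scheme()]; built from the index and
#'   `params` when omitted.
#' @param cache optional [new_kmer_cache()].
#' @return list with `status` ("mapped", "unmapped", "multimapped") and
#'   `fragment` (a one-row `data.table`, or NULL).
#' @export
map_pair <- function(index, r1, r3, barcode = NA_character_,
                     params = map_params(), scheme = NULL, cache = NULL) {
  res <- map_pairs(index, r1, r3, barcodes = barcode, params = params,
                   scheme = scheme, cache = cache)
  status <- c("mapped", "unmapped", "multimapped")[res$status + 1L]
  list(status = status,
       fragment = if (status == "mapped") res$fragments else NULL)
}

#' Map a batch of read pairs
#'
#' Vectorized paired-end mapping: the whole
#' pseudoalign/dedup/merge/filter pipeline runs per pair in compiled code.
#' The virtual-color scheme is computed on the fly from the index's
#' reference lengths; when `params$ov_length` is NULL the overlap defaults
#' to `max(150, 2 * max observed read length)`.
#'
#' @param index a [build_index()] result.
#' @param r1,r3 character vectors of mate sequences (optionally named with
#'   read ids; `r1` names are used as `read_id`).
#' @param barcodes optional character vector of cell barcodes per pair.
#' @param params a [map_params()].
#' @param scheme optional [build_scheme()] overriding the on-the-fly one.
#' @param cache optional shared [new_kmer_cache()]; when NULL and caching
#'   is enabled a fresh cache of `params$cache_capacity` entries is used.
#' @return list of class `map_result`: `fragments` (`data.table` with
#'   `read_id`, `barcode`, `ref_id`, `ref`, `start`, `end`, `ori`, `frac`),
#'   `status` (integer per pair: 0 mapped, 1 unmapped, 2 multimapped),
#'   `stats` (counts and mapping rate) and `scheme`.
#' @export
map_pairs <- function(index, r1, r3, barcodes = NULL, params = map_params(),
                      scheme = NULL, cache = NULL) {
  stopifnot(inherits(index, "dbg_index"), inherits(params, "map_params"))
  if (length(r1) != length(r3))
    stop("mate vectors r1 and r3 have different lengths")
  if (params$k != index$k)
    warning("params$k (", params$k, ") differs from the index k (", index$k,
            "); the index k governs mapping")
  nm1 <- names(r1)
  r1 <- as.character(r1); names(r1) <- nm1
  r3 <- as.character(r3)
  if (is.null(scheme)) {
    ov <- params$ov_length %||%
      max(150L, 2L * suppressWarnings(max(nchar(r1), nchar(r3), 0L)))
    ov <- min(ov, params$lvcol)
    scheme <- build_scheme(index$ref_len, lvcol = params$lvcol,
                           ov_length = ov)
  }
  if (params$premerge_mates)
    warning("premerge_mates is not applied by map_pairs(); use ",
            "merge_overlapping_mates() explicitly before mapping")
  if (is.null(cache) && params$use_cache && params$streaming)
    cache <- new_kmer_cache(params$cache_capacity)
  if (!params$use_cache) cache <- NULL
  r <- .map_pairs_cpp(unclass(index), r1, r3, scheme$CB, scheme$B,
                      scheme$lvcol, scheme$ov_length, params$tau,
                      params$dovetail_max, params$ins_max,
                      params$streaming, .cache_ptr(cache))
  if (r$dup_violation > 0L)
    stop("internal invariant violation: ", r$dup_violation,
         " duplicate hit group(s) of size > 2")
  ids <- names(r1) %||% sprintf("pair%d", seq_along(r1))
  if (is.null(names(r1))) names(r1) <- ids
  bc <- if (is.null(barcodes)) rep(NA_character_, length(r1)) else
    as.character(barcodes)
  frags <- data.table(
    read_id = ids[r$pair], barcode = bc[r$pair], ref_id = r$ref,
    ref = index$ref_names[r$ref + 1L], start = r$start, end = r$end,
    ori = c("r", "f")[r$fwd1 + 1L], frac = r$frac)
  n <- length(r1)
  stats <- list(n_pairs = n, mapped = sum(r$status == 0L),
                unmapped = sum(r$status == 1L),
                multimapped = sum(r$status == 2L),
                mapping_rate = if (n) sum(r$status == 0L) / n else NA_real_)
  structure(list(fragments = frags, status = r$status, stats = stats,
                 scheme = scheme),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("map_result: %d pairs; %d mapped (%.2f%%), ",
                     "%d unmapped, %d multimapped\n"),
              s$n_pairs, s$mapped, 100 * s$mapping_rate, s$unmapped,
              s$multimapped))
  invisible(x)
}

#' Map a 10x-layout FASTQ triple
#'
#' Reads R1 (genomic mate 1), R2 (cell barcode) and R3 (genomic mate 2)
#' FASTQ files (optionally gzipped) and maps every pair with
#' [map_pairs()].
#'
#' @param index a [build_index()] result.
#' @param r1_path,r2_path,r3_path FASTQ paths in 10x scATAC layout.
#' @param params a [map_params()].
#' @param cache optional shared [new_kmer_cache()].
#' @return a `map_result` (see [map_pairs()]).
#' @export
map_fastq <- function(index, r1_path, r2_path, r3_path,
                      params = map_params(), cache = NULL) {
  rd <- function(p) {
    ss <- Biostrings::readDNAStringSet(p, format = "fastq")
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  r1 <- rd(r1_path); r2 <- rd(r2_path); r3 <- rd(r3_path)
  if (length(r1) != length(r2) || length(r1) != length(r3))
    stop("FASTQ files disagree on the number of reads (R1: ", length(r1),
         ", R2: ", length(r2), ", R3: ", length(r3), ")")
  map_pairs(index, r1, r3, barcodes = unname(r2), params = params,
            cache = cache)
}

#' Optional pre-mapping merge of overlapping mates
#'
#' Attempts to merge each read pair into a unified fragment before
#' mapping: mate 2 is reverse-complemented and the longest 3'-overlap of
#' at least `min_overlap` bases with at most `max_mismatch` mismatches is
#' taken; on success the merged sequence can be mapped single-end with the
#' same threshold rule. This stage is off by default and excluded from the
#' package's accuracy properties; its parameters are this package's own.
#'
#' @param r1,r3 character vectors of mate sequences.
#' @param min_overlap minimum 3'-overlap in bases.
#' @param max_mismatch maximum mismatches tolerated in the overlap.
#' @return list with `merged` (merged sequence or NA per pair) and
#'   `overlap` (overlap length used, 0 when unmerged).
#' @export
merge_overlapping_mates <- function(r1, r3, min_overlap = 20L,
                                    max_mismatch = 2L) {
  stopifnot(length(r1) == length(r3))
  rc3 <- revcomp(r3)
  merged <- rep(NA_character_, length(r1))
  ovl <- integer(length(r1))
  for (i in seq_along(r1)) {
    a <- r1[i]; b <- rc3[i]
    la <- nchar(a); lb <- nchar(b)
    if (min(la, lb) < min_overlap) next
    for (o in seq.int(min(la, lb), min_overlap)) {
      sa <- strsplit(substr(a, la - o + 1L, la), "")[[1L]]
      sb <- strsplit(substr(b, 1L, o), "")[[1L]]
      if (sum(sa != sb) <= max_mismatch) {
        merged[i] <- paste0(a, substr(b, o + 1L, lb))
        ovl[i] <- o
        break
      }
    }
  }
  list(merged = merged, overlap = ovl)
}
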