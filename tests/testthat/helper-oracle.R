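# Independent oracles built by naive full-text enumeration: a dictionary of
# every genome k-mer with its positions, and a literal transcription of the
# threshold-union pseudoalignment definition over virtual-color intervals.
# Nothing here touches the de Bruijn graph machinery under test.

library(data.table)

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

read_kmers <- function(read, k) {
  rl <- nchar(read)
  if (rl < k) return(character(0))
  substring(read, 1:(rl - k + 1L), k:rl)
}

# kmer -> (ref, pos) table of every as-written genome k-mer (N-mers excluded)
genome_kmer_dict <- function(refs, k) {
  dt <- rbindlist(lapply(seq_along(refs$seqs), function(i) {
    km <- read_kmers(refs$seqs[i], k)
    data.table(kmer = km, ref = i - 1L, pos = seq_along(km) - 1L)
  }))
  dt <- dt[!grepl("[^ACGT]", kmer)]
  setkey(dt, kmer)
  dt
}

# all (ref, pos, ori) occurrences of each query k-mer by dictionary lookup
oracle_occurrences <- function(dict, kmers) {
  lapply(kmers, function(km) {
    if (grepl("[^ACGT]", km) || nchar(km) == 0L)
      return(data.table(ref = integer(0), pos = integer(0), ori = character(0)))
    f <- dict[.(km), nomatch = NULL][, .(ref, pos, ori = "f")]
    r <- dict[.(vcatac::revcomp(km)), nomatch = NULL][, .(ref, pos, ori = "r")]
    rbind(f, r)
  })
}

# virtual-color interval of bin b on a reference, straight from the formula
oracle_bin_interval <- function(b, lvcol, ov, L) {
  c(start = max(0L, b * lvcol - ov), end = min(L, (b + 1L) * lvcol))
}

# literal threshold-union pseudoalignment over virtual colors; `occs` as
# produced by oracle_occurrences for the read's k-mers
oracle_pseudoalign <- function(refs, occs, rl, k, tau, lvcol, ov) {
  L <- refs$L
  B <- ceiling(L / lvcol)
  CB <- cumsum(c(0, B[-length(B)]))
  kq <- sum(vapply(occs, nrow, integer(1)) > 0L)
  if (kq == 0L) {
    return(data.table(ref = integer(0), pos = integer(0), ori = character(0),
                      vid = integer(0), support = integer(0), kq = integer(0)))
  }
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(occs)) {
    oc <- occs[[i]]
    if (nrow(oc) == 0L) next
    off <- i - 1L
    for (j in seq_len(nrow(oc))) {
      r <- oc$ref[j]; p <- oc$pos[j]; ori <- oc$ori[j]
      for (b in 0:(B[r + 1L] - 1L)) {
        iv <- oracle_bin_interval(b, lvcol, ov, L[r + 1L])
        if (p < iv[["start"]] || p >= iv[["end"]]) next
        key <- paste(CB[r + 1L] + b, ori)
        e <- acc[[key]]
        if (is.null(e)) {
          acc[[key]] <- list(ref = r, vid = CB[r + 1L] + b, ori = ori,
                             kset = off, first = off, minpos = p)
        } else {
          e$kset <- union(e$kset, off)
          if (off == e$first) e$minpos <- min(e$minpos, p)
          acc[[key]] <- e
        }
      }
    }
  }
  rows <- lapply(ls(acc), function(key) {
    e <- acc[[key]]
    support <- length(e$kset)
    if (support + 1e-9 < tau * kq) return(NULL)
    pos <- if (e$ori == "f") e$minpos - e$first else
      e$minpos - (rl - k - e$first)
    data.table(ref = e$ref, pos = max(0L, as.integer(pos)), ori = e$ori,
               vid = as.integer(e$vid), support = support, kq = kq)
  })
  out <- rbindlist(rows)
  if (nrow(out)) setorder(out, vid, ori)
  out[]
}

# apply the oracle to a read (builds occurrences from the dictionary)
oracle_map_read <- function(refs, dict, read, k, tau, lvcol, ov) {
  occs <- oracle_occurrences(dict, read_kmers(read, k))
  oracle_pseudoalign(refs, occs, nchar(read), k, tau, lvcol, ov)
}

# draw a read from the genome with optional substitutions / strand flip
sample_read <- function(refs, rl, n_err = 0L, reverse = FALSE) {
  r <- sample.int(length(refs$seqs), 1L)
  s <- sample.int(refs$L[r] - rl + 1L, 1L)
  rd <- substr(refs$seqs[r], s, s + rl - 1L)
  if (n_err > 0L) {
    ch <- strsplit(rd, "")[[1L]]
    pos <- sample.int(rl, n_err)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    rd <- paste(ch, collapse = "")
  }
  if (reverse) rd <- vcatac::revcomp(rd)
  list(read = rd, ref = r - 1L, start = s - 1L)
}

# reconstruct one reference from its unitig tiling; NA where uncovered
stitch_reference <- function(idx, r) {
  L <- idx$ref_len[r + 1L]
  out <- rep(NA_character_, L)
  for (u in seq_along(idx$unitigs)) {
    lo <- idx$occ_ptr[u]; hi <- idx$occ_ptr[u + 1L]
    if (hi <= lo) next
    for (j in (lo + 1L):hi) {
      if (idx$occ_ref[j] != r) next
      useq <- idx$unitigs[u]
      if (!idx$occ_fwd[j]) useq <- vcatac::revcomp(useq)
      ch <- strsplit(useq, "")[[1L]]
      tgt <- (idx$occ_pos[j] + 1L):(idx$occ_pos[j] + nchar(useq))
      prev <- out[tgt]
      if (any(!is.na(prev) & prev != ch))
        stop("conflicting unitig occurrences at reference ", r)
      out[tgt] <- ch
    }
  }
  out
}
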