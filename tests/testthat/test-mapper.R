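# mapper: streaming queries, cache semantics, pseudoalignment, dedup,
# mate merging, best-support filtering, pair orchestration

make_branchy_genome <- function(seed = 21) {
  # a duplicated segment forces unitig breaks at its boundaries
  set.seed(seed)
  seg <- rand_dna(120)
  reference_set(c(g = paste0(rand_dna(1500), seg, rand_dna(1200), seg,
                             rand_dna(800))))
}

test_that("streaming query equals independent lookups and saves index queries", {
  refs <- make_branchy_genome()
  idx <- build_index(refs, k = 25)
  naive_slots <- function(read) {
    lookup_kmer(idx, read_kmers(read, 25L))[, .(present, unitig, off, ori)]
  }
  strip <- function(d) {
    d <- as.data.frame(d)
    attributes(d) <- attributes(d)[c("names", "class", "row.names")]
    d
  }
  # (a) read fully inside one unitig: one query, the rest by extension
  long_u <- which.max(idx$unitig_len)
  read_in <- substr(idx$unitigs[long_u], 10, 10 + 49)
  got <- query_kmers_streaming(idx, read_in)
  expect_equal(strip(got), strip(naive_slots(read_in)))
  expect_equal(attr(got, "n_queries"), 1L)
  expect_equal(attr(query_kmers_streaming(idx, read_in, streaming = FALSE),
                    "n_queries"), 26L)
  # (b) read spanning a unitig junction: extension fails exactly there
  jpos <- 1501 - 30  # straddles the start of the duplicated segment
  read_jn <- substr(refs$seqs[1], jpos, jpos + 70)
  got_jn <- query_kmers_streaming(idx, read_jn)
  expect_equal(strip(got_jn), strip(naive_slots(read_jn)))
  expect_gt(attr(got_jn, "n_queries"), 1L)
  # (c) substitution mid-read: covering k-mers come back empty
  read_mm <- substr(refs$seqs[1], 3001, 3080)
  substr(read_mm, 40, 40) <- chartr("ACGT", "TGCA", substr(read_mm, 40, 40))
  got_mm <- query_kmers_streaming(idx, read_mm)
  expect_equal(strip(got_mm), strip(naive_slots(read_mm)))
  expect_true(any(!got_mm$present))
  # (d) non-ACGT k-mers yield empty slots, no error
  read_n <- paste0(substr(refs$seqs[1], 101, 140), "N",
                   substr(refs$seqs[1], 141, 180))
  got_n <- query_kmers_streaming(idx, read_n)
  expect_equal(strip(got_n), strip(naive_slots(read_n)))
})

test_that("terminal k-mer cache is write-once, bounded, and output-neutral", {
  refs <- make_branchy_genome(33)
  idx <- build_index(refs, k = 25)
  reads <- vapply(1:200, function(i) {
    s <- sample.int(refs$L[1] - 100, 1L)
    substr(refs$seqs[1], s, s + 99)
  }, character(1))
  cache <- new_kmer_cache(capacity = 50)
  with_cache <- lapply(reads, function(rd)
    query_kmers_streaming(idx, rd, cache = cache))
  without <- lapply(reads, function(rd) query_kmers_streaming(idx, rd))
  strip <- function(d) {
    d <- as.data.frame(d)
    attributes(d) <- attributes(d)[c("names", "class", "row.names")]
    d
  }
  expect_identical(lapply(with_cache, strip), lapply(without, strip))
  expect_lte(cache_size(cache), 50)
  expect_equal(cache_capacity(cache), 50)
  ent <- cache_entries(cache, 25L)
  expect_gt(nrow(ent), 0L)
  # every cached value equals a fresh index lookup of the canonical key
  fresh <- lookup_kmer(idx, ent$kmer)
  expect_true(all(fresh$present))
  expect_equal(ent$uid, fresh$unitig)
  expect_equal(ent$off, fresh$off)
  # cached keys are canonical, so the stored orientation is canonical-vs-
  # unitig, which lookup_kmer reports for the canonical query string
  expect_equal(c("r", "f")[ent$fwd + 1L], fresh$ori)
  # write-once: re-running the same reads never changes existing entries
  sz <- cache_size(cache)
  for (rd in reads) query_kmers_streaming(idx, rd, cache = cache)
  expect_identical(cache_entries(cache, 25L), ent)
  expect_equal(cache_size(cache), sz)
})

test_that("threshold-union keeps only sufficiently supported virtual colors", {
  # segment X (5 k-mers) in bin 5; its first 3 k-mers also occur in bin 1
  set.seed(77)
  k <- 25L
  x <- rand_dna(k + 4)          # 5 k-mers
  x_part <- substr(x, 1, k + 2) # first 3 k-mers
  bg <- function(n) rand_dna(n)
  g <- paste0(bg(1300), x_part, bg(5100 - 1300 - nchar(x_part)), x, bg(2000))
  refs <- reference_set(c(g = g))
  idx <- build_index(refs, k = 25)
  sc <- build_scheme(refs, lvcol = 1000, ov_length = 0)
  hits <- pseudoalign_mate(idx, sc, x, tau = 0.7)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$vid, 5L)
  expect_equal(hits$pos, 5100L)
  expect_equal(hits$support, 5L)
  expect_equal(hits$kq, 5L)
  # at a permissive threshold the partial copy shows up too
  hits_low <- pseudoalign_mate(idx, sc, x, tau = 0.5)
  expect_equal(sort(hits_low$vid), c(1L, 5L))
  # the partial-copy hit is anchored on the leftmost (first) k-mer in bin 1
  expect_equal(hits_low[vid == 1L]$pos, 1300L)
})

test_that("K(Q) counts only index-matched k-mers, so tau = 1 survives errors", {
  set.seed(78)
  refs <- reference_set(c(g = rand_dna(8000)))
  idx <- build_index(refs, k = 25)
  sc <- build_scheme(refs, lvcol = 1000, ov_length = 150)
  read <- substr(refs$seqs[1], 2001, 2100)
  substr(read, 50, 50) <- chartr("ACGT", "TGCA", substr(read, 50, 50))
  hits <- pseudoalign_mate(idx, sc, read, tau = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos, 2000L)
  expect_lt(hits$kq, 76L)           # error k-mers are excluded from K(Q)
  expect_equal(hits$support, hits$kq)
  # all-N and too-short reads are unmapped, not errors
  expect_equal(nrow(pseudoalign_mate(idx, sc, strrep("N", 80), tau = 1)), 0L)
  expect_equal(nrow(pseudoalign_mate(idx, sc, "ACGT", tau = 1)), 0L)
})

test_that("pseudoalignment equals the literal brute-force oracle", {
  set.seed(101)
  for (trial in 1:4) {
    seg <- rand_dna(80)
    refs <- reference_set(c(
      a = paste0(rand_dna(1200), seg, rand_dna(900), seg, rand_dna(400)),
      b = rand_dna(1700)))
    idx <- build_index(refs, k = 15)
    dict <- genome_kmer_dict(refs, 15L)
    sc <- build_scheme(refs, lvcol = 500, ov_length = 100)
    for (i in 1:10) {
      rd <- sample_read(refs, 60, n_err = sample(0:2, 1),
                        reverse = runif(1) < 0.5)$read
      for (tau in c(0.6, 1)) {
        got <- pseudoalign_mate(idx, sc, rd, tau = tau)
        exp <- oracle_map_read(refs, dict, rd, 15L, tau, 500L, 100L)
        expect_equal(as.data.frame(got), as.data.frame(exp),
                     info = paste("trial", trial, "read", i, "tau", tau))
      }
    }
  }
})

test_that("duplicate hits collapse to the smaller virtual color id", {
  h <- function(ref, pos, ori, vid, support = 5L, kq = 5L)
    data.table(ref = ref, pos = pos, ori = ori, vid = vid,
               support = support, kq = kq)
  # overlap-induced duplicate: keep vid 0
  d <- dedup_hits(rbind(h(0L, 950L, "f", 0L), h(0L, 950L, "f", 1L)))
  expect_equal(d$vid, 0L)
  # distinct positions: unchanged
  d2 <- dedup_hits(rbind(h(0L, 100L, "f", 0L), h(0L, 700L, "f", 0L)))
  expect_equal(nrow(d2), 2L)
  # opposite orientations at one position: both kept
  d3 <- dedup_hits(rbind(h(0L, 950L, "f", 0L), h(0L, 950L, "r", 0L)))
  expect_equal(nrow(d3), 2L)
  # groups larger than two violate the construction guarantee
  expect_error(dedup_hits(rbind(h(0L, 950L, "f", 0L), h(0L, 950L, "f", 1L),
                                h(0L, 950L, "f", 2L))),
               "invariant")
})

test_that("mate merging enforces reference, color adjacency, orientation and extent", {
  h <- function(ref, pos, ori, vid, support = 70L, kq = 76L)
    data.table(ref = ref, pos = pos, ori = ori, vid = vid,
               support = support, kq = kq)
  m <- merge_mates(h(0L, 100L, "f", 0L), h(0L, 380L, "r", 0L), 50L, 50L)
  expect_equal(m[, .(ref, start, end)],
               data.table(ref = 0L, start = 100L, end = 430L))
  expect_equal(m$ori1, "f")
  expect_equal(m$frac, 140 / 152)
  # dovetail within bounds merges
  expect_equal(nrow(merge_mates(h(0L, 100L, "f", 0L), h(0L, 90L, "r", 0L),
                                50L, 50L)), 1L)
  # beyond the insert bound does not
  expect_equal(nrow(merge_mates(h(0L, 100L, "f", 0L), h(0L, 1200L, "r", 0L),
                                50L, 50L)), 0L)
  # same orientation, different reference, distant colors all fail
  expect_equal(nrow(merge_mates(h(0L, 100L, "f", 0L), h(0L, 380L, "f", 0L),
                                50L, 50L)), 0L)
  expect_equal(nrow(merge_mates(h(0L, 100L, "f", 0L), h(1L, 380L, "r", 5L),
                                50L, 50L)), 0L)
  expect_equal(nrow(merge_mates(h(0L, 100L, "f", 0L), h(0L, 380L, "r", 2L),
                                50L, 50L)), 0L)
  # adjacent colors merge; reversed mate-1 swaps the position constraint
  expect_equal(nrow(merge_mates(h(0L, 950L, "f", 0L), h(0L, 1100L, "r", 1L),
                                50L, 50L)), 1L)
  expect_equal(nrow(merge_mates(h(0L, 380L, "r", 0L), h(0L, 100L, "f", 0L),
                                50L, 50L)), 1L)
})

test_that("best-support filtering keeps exactly the tau-prime stratum", {
  m <- data.table(ref = 0L, start = c(100L, 900L), end = c(350L, 1150L),
                  ori1 = "f", frac = c(1.0, 0.8))
  expect_equal(filter_best_support(m)$start, 100L)
  expect_equal(filter_best_support(m[1]), m[1])
  ties <- data.table(ref = 0L, start = c(100L, 900L), end = c(350L, 1150L),
                     ori1 = "f", frac = c(1.0, 1.0))
  expect_equal(nrow(filter_best_support(ties)), 2L)
  expect_equal(nrow(filter_best_support(m[0])), 0L)
})

test_that("map_pair resolves unique pairs and discards ambiguous ones", {
  set.seed(55)
  seg <- rand_dna(600)  # long enough to hold a whole fragment
  refs <- reference_set(c(
    g = paste0(rand_dna(3000), seg, rand_dna(2400), seg, rand_dna(1000))))
  idx <- build_index(refs, k = 25)
  # unique-origin error-free pair maps to its true fragment
  fs <- 1201L; fe <- 1500L
  r1 <- substr(refs$seqs[1], fs, fs + 99)
  r3 <- revcomp(substr(refs$seqs[1], fe - 99, fe))
  res <- map_pair(idx, r1, r3, barcode = "AAAA")
  expect_equal(res$status, "mapped")
  expect_equal(res$fragment$start, fs - 1L)
  expect_equal(res$fragment$end, fe)
  expect_equal(res$fragment$ori, "f")
  # a pair fully inside the duplicated segment ties and is discarded
  ds <- 3001L + 150L
  d1 <- substr(refs$seqs[1], ds, ds + 99)
  d3 <- revcomp(substr(refs$seqs[1], ds + 150, ds + 249))
  expect_equal(map_pair(idx, d1, d3)$status, "multimapped")
  # mates from different references cannot merge
  refs2 <- reference_set(c(a = rand_dna(2000), b = rand_dna(2000)))
  idx2 <- build_index(refs2, k = 25)
  m1 <- substr(refs2$seqs[1], 501, 600)
  m3 <- revcomp(substr(refs2$seqs[2], 501, 600))
  expect_equal(map_pair(idx2, m1, m3)$status, "unmapped")
})

test_that("lowering tau never removes a surviving (vid, ori) pair", {
  set.seed(91)
  seg <- rand_dna(60)
  refs <- reference_set(c(
    g = paste0(rand_dna(2000), seg, rand_dna(1500), seg, rand_dna(500))))
  idx <- build_index(refs, k = 15)
  sc <- build_scheme(refs, lvcol = 1000, ov_length = 150)
  for (i in 1:25) {
    rd <- sample_read(refs, 60, n_err = sample(0:3, 1),
                      reverse = runif(1) < 0.5)$read
    prev <- NULL
    for (tau in c(1, 0.8, 0.7, 0.6)) {
      cur <- pseudoalign_mate(idx, sc, rd, tau = tau)[, paste(vid, ori)]
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("streaming and cache toggles leave batch mapping output unchanged", {
  sp <- sim_params(genome_length = 50000, n_pairs = 300, seed = 12,
                   substitution_rate = 0.01)
  g <- make_genome(sp)
  sim <- simulate_pairs(g, sp)
  idx <- build_index(g$refs, k = 25)
  outs <- lapply(list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                      c(FALSE, FALSE)), function(fl) {
    p <- map_params(streaming = fl[1], use_cache = fl[2])
    r <- map_pairs(idx, sim$r1, sim$r3, barcodes = sim$r2, params = p)
    list(frags = as.data.frame(r$fragments), status = r$status)
  })
  for (i in 2:4) expect_identical(outs[[i]], outs[[1]])
})

test_that("mismatched mate vectors and FASTQ triples are rejected", {
  refs <- reference_set(c(g = strrep("ACGTG", 200)))
  suppressWarnings(idx <- build_index(refs, k = 15))
  expect_error(map_pairs(idx, c("ACGT", "ACGT"), "ACGT"), "different lengths")
})

test_that("optional pre-mapping mate merge joins overlapping pairs only", {
  set.seed(66)
  g <- rand_dna(400)
  frag <- substr(g, 101, 250)              # 150 bp fragment
  r1 <- substr(frag, 1, 100)
  r3 <- revcomp(substr(frag, 51, 150))     # 50 bp 3'-overlap
  mm <- merge_overlapping_mates(r1, r3)
  expect_equal(mm$overlap, 50L)
  expect_equal(mm$merged, frag)
  # disjoint mates do not merge
  mm2 <- merge_overlapping_mates(substr(g, 1, 60), revcomp(substr(g, 200, 260)))
  expect_true(is.na(mm2$merged))
  expect_equal(mm2$overlap, 0L)
})
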