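# fragment processing: barcode correction, sorting, dedup, BED I/O

rand_frags <- function(n, n_ref = 3L, bcs = c("AAAA", "CCCC", "GGGG")) {
  data.table(read_id = sprintf("p%05d", seq_len(n)),
             barcode = sample(bcs, n, replace = TRUE),
             ref_id = sample.int(n_ref, n, replace = TRUE) - 1L,
             ref = "",
             start = sample.int(10000L, n, replace = TRUE),
             end = 0L, ori = sample(c("f", "r"), n, replace = TRUE),
             frac = round(runif(n), 3))[, `:=`(
               ref = paste0("ref", ref_id + 1L),
               end = start + sample(50:500, n, replace = TRUE))][]
}

test_that("barcode correction keeps members, rescues unique neighbors, drops ties", {
  pl <- permit_list(c("AAAA", "CCCC", "AACA", "AACG"))
  expect_equal(correct_barcode("AAAA", pl), "AAAA")
  expect_equal(correct_barcode("AAAT", pl), "AAAA")  # unique Hamming-1
  expect_true(is.na(correct_barcode("AACC", pl)))    # AACA/AACG tie
  expect_true(is.na(correct_barcode("GGGG", pl)))    # no neighbor
  expect_true(is.na(correct_barcode("AAAAA", pl)))   # length mismatch
  # vectorized form preserves order
  expect_equal(correct_barcode(c("AAAA", "AAAT", "AACC"), pl),
               c("AAAA", "AAAA", NA))
})

test_that("the frequency policy breaks ties by exact-match abundance", {
  pl <- permit_list(c("AACA", "AACG"))
  expect_true(is.na(correct_barcode("AACC", pl, policy = "unique")))
  got <- correct_barcode(c("AACA", "AACA", "AACG", "AACC"), pl,
                         policy = "frequency")
  expect_equal(got[4], "AACA")  # AACA seen twice exactly, AACG once
  # equal counts still drop
  tie <- correct_barcode(c("AACA", "AACG", "AACC"), pl, policy = "frequency")
  expect_true(is.na(tie[3]))
  # explicit counts override observation
  got2 <- correct_barcode("AACC", pl, policy = "frequency",
                          exact_counts = c(AACG = 5L, AACA = 1L))
  expect_equal(got2, "AACG")
})

test_that("correct_barcodes reports conservation counts", {
  pl <- permit_list(c("AAAA", "CCCC"))
  fr <- data.table(barcode = c("AAAA", "AAAT", "GGGG", "CCCC"),
                   ref_id = 0L, ref = "r", start = 1:4, end = 11:14)
  res <- correct_barcodes(fr, pl)
  expect_equal(res$stats$n_in, 4L)
  expect_equal(res$stats$n_exact, 2L)
  expect_equal(res$stats$n_rescued, 1L)
  expect_equal(res$stats$n_dropped, 1L)
  expect_equal(nrow(res$fragments),
               res$stats$n_in - res$stats$n_dropped)
  expect_true(all(res$fragments$barcode %in% as.character(pl)))
})

test_that("sorting is stable, total, and identical for any chunk size", {
  set.seed(19)
  fr <- rand_frags(10000)
  ordered <- sort_fragments(fr)
  # already-sorted input is unchanged; reverse-sorted input is restored
  expect_equal(as.data.frame(sort_fragments(ordered)), as.data.frame(ordered))
  expect_equal(as.data.frame(sort_fragments(ordered[.N:1])),
               as.data.frame(ordered))
  # external-memory path is identical to the in-memory sort
  ext <- sort_fragments(fr, chunk_size = 1000)
  expect_identical(as.data.frame(ext), as.data.frame(ordered))
  small <- rand_frags(60)
  for (cs in c(7, 1)) {
    ext <- sort_fragments(small, chunk_size = cs)
    expect_identical(as.data.frame(ext),
                     as.data.frame(sort_fragments(small)),
                     info = paste("chunk size", cs))
  }
  # total order respected
  expect_true(all(diff(ordered$ref_id) >= 0))
  expect_error(sort_fragments(fr[, !"start"]), "lack column")
  expect_equal(nrow(sort_fragments(fr[0])), 0L)
})

test_that("dedup collapses equal fragments, counts sum, unsorted input rejected", {
  fr <- data.table(read_id = sprintf("p%d", 1:6),
                   barcode = c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG", "AAAA"),
                   ref_id = 0L, ref = "chr1",
                   start = c(100L, 100L, 100L, 100L, 100L, 900L),
                   end = c(430L, 430L, 430L, 430L, 430L, 1200L))
  sorted <- sort_fragments(fr)
  bed <- dedup_fragments(sorted)
  expect_equal(nrow(bed), 4L)
  expect_equal(bed[start == 100L & barcode == "AAAA"]$count, 3L)
  expect_equal(bed[start == 100L & barcode == "CCCC"]$count, 1L)
  expect_equal(sum(bed$count), nrow(fr))
  expect_equal(nrow(dedup_fragments(fr[0])), 0L)
  expect_error(dedup_fragments(fr[c(6, 1, 2, 3, 4, 5)]), "sorted")
  # idempotence: a deduplicated BED re-processed as fragments is unchanged
  again <- dedup_fragments(sort_fragments(
    bed[, .(read_id = "x", barcode, ref_id = 0L, ref = chrom, start, end)]))
  expect_equal(again[, .(chrom, start, end, barcode)],
               bed[, .(chrom, start, end, barcode)])
  expect_true(all(again$count == 1L))
})

test_that("BED round trip preserves records and read validates lines", {
  set.seed(31)
  fr <- rand_frags(1000)
  bed <- dedup_fragments(sort_fragments(fr))
  expect_equal(bed$chrom[1], fr[order(ref_id, start, end, barcode)]$ref[1])
  for (ext in c(".bed", ".bed.gz")) {
    f <- tempfile(fileext = ext)
    write_bed(bed, f)
    back <- read_bed(f)
    expect_equal(as.data.frame(back), as.data.frame(bed))
  }
  # a single literal record
  one <- data.table(chrom = "chr1", start = 100L, end = 430L,
                    barcode = "AAAA", count = 3L)
  f1 <- tempfile(fileext = ".bed")
  write_bed(one, f1)
  expect_equal(readLines(f1), "chr1\t100\t430\tAAAA\t3")
  # malformed inputs: negative start, non-integer field
  fbad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tAAAA\t1", "chr1\t-5\t20\tAAAA\t1"), fbad)
  expect_error(read_bed(fbad), "line 2")
  writeLines("chr1\tten\t20\tAAAA\t1", fbad)
  expect_error(read_bed(fbad), "non-integer")
})

test_that("process_fragments conserves counts end to end and can shift Tn5", {
  set.seed(47)
  pl <- permit_list(replicate(50, rand_dna(8)))
  n <- 400L
  bcs <- sample(as.character(pl), n, replace = TRUE)
  err <- sample(n, 60)  # inject one-base errors in a subset
  for (i in err) {
    p <- sample.int(8L, 1L)
    substr(bcs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(bcs[i], p, p)), 1L)
  }
  fr <- data.table(read_id = sprintf("p%04d", 1:n), barcode = bcs,
                   ref_id = sample(0:1, n, TRUE), ref = "chr",
                   start = sample.int(5000L, n, TRUE), ori = "f",
                   frac = 1)[, ref := paste0("chr", ref_id + 1L)][,
                   end := start + 200L][]
  res <- process_fragments(fr, pl, chunk_size = 128)
  st <- res$stats
  expect_equal(st$n_in, st$n_exact + st$n_rescued + st$n_dropped)
  expect_equal(st$sum_counts, st$n_in - st$n_dropped)
  expect_equal(sum(res$bed$count), st$sum_counts)
  # Tn5 shift moves both ends inward by the +4/-5 convention
  res5 <- process_fragments(fr[1:10], pl, tn5_shift = TRUE)
  plain <- process_fragments(fr[1:10], pl)
  keep <- plain$bed$barcode %in% res5$bed$barcode
  expect_equal(res5$bed$start, plain$bed$start[keep] + 4L)
  expect_equal(res5$bed$end, plain$bed$end[keep] - 5L)
  # fragment TSV round trip feeds the same pipeline
  tsv <- tempfile(fileext = ".tsv")
  write_fragments(fr, tsv)
  res2 <- process_fragments(tsv, pl, chunk_size = 1e9)
  expect_equal(as.data.frame(res2$bed), as.data.frame(res$bed))
})
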