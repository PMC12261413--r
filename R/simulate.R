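#' Simulation parameters
#'
#' Settings for the synthetic genome and read generator used to exercise
#' and score the mapping pipeline. The generator emulates the structure of
#' a droplet scATAC-seq experiment: a genome with tunable repeat content,
#' FR-oriented paired-end fragments with i.i.d. substitution errors, and
#' cell barcodes drawn from a permit list with occasional one-base errors.
#'
#' @param genome_length total genome length in bases.
#' @param n_refs number of reference sequences (the genome is split
#'   evenly).
#' @param repeats optional repeat specification:
#'   `list(count =, length =, divergence =, families =)` -- `count` copies
#'   per family of a `length`-base element; the first copy is the family
#'   consensus and each later copy carries i.i.d. substitutions at rate
#'   `divergence` relative to it.
#' @param fragment_mean,fragment_sd fragment length distribution in bases
#'   (normal, floored at `read_length`).
#' @param read_length genomic mate length in bases.
#' @param substitution_rate per-base substitution probability in the
#'   genomic mates.
#' @param n_pairs number of read pairs.
#' @param barcode_n,barcode_length permit-list size and barcode length.
#' @param barcode_error_rate probability that an observed barcode carries
#'   a single-base error.
#' @param duplicate_rate probability that a fragment is emitted a second
#'   time (an exact PCR-style duplicate with independently re-drawn read
#'   and barcode errors).
#' @param n_gaps,n_gap_length optionally overwrite this many stretches of
#'   the genome with N, to exercise contig splitting.
#' @param seed integer seed (< 2^30); `make_genome()` uses `seed`,
#'   `simulate_pairs()` uses `seed + 1`, so the pair (genome, reads) is
#'   fully reproducible.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(genome_length = 1e6, n_refs = 1L, repeats = NULL,
                       fragment_mean = 250, fragment_sd = 60,
                       read_length = 100L, substitution_rate = 0.005,
                       n_pairs = 20000L, barcode_n = 500L,
                       barcode_length = 16L, barcode_error_rate = 0.02,
                       duplicate_rate = 0, n_gaps = 0L, n_gap_length = 0L,
                       seed = 1L) {
  p <- list(genome_length = as.numeric(genome_length),
            n_refs = as.integer(n_refs), repeats = repeats,
            fragment_mean = fragment_mean, fragment_sd = fragment_sd,
            read_length = as.integer(read_length),
            substitution_rate = substitution_rate,
            n_pairs = as.integer(n_pairs),
            barcode_n = as.integer(barcode_n),
            barcode_length = as.integer(barcode_length),
            barcode_error_rate = barcode_error_rate,
            duplicate_rate = duplicate_rate,
            n_gaps = as.integer(n_gaps),
            n_gap_length = as.integer(n_gap_length),
            seed = as.integer(seed))
  for (f in c("substitution_rate", "barcode_error_rate", "duplicate_rate"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (!is.null(seed) && abs(p$seed) >= 2^30) stop("seed must be < 2^30")
  structure(p, class = "sim_params")
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_chars <- function(chars, rate) {
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    chars[hit] <- alt[cbind(sample.int(3L, length(hit), replace = TRUE),
                            match(chars[hit], colnames(alt)))]
  }
  chars
}

#' Generate a synthetic genome
#'
#' An i.i.d. uniform-ACGT background with, optionally, repeat families
#' overwritten at recorded non-overlapping positions (each copy carrying
#' i.i.d. divergence relative to the family consensus) and N gaps.
#' Deterministic under `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list with `refs` (a [reference_set()]) and `repeat_info`
#'   (`data.table` of family, copy, ref_id, start, end).
#' @export
make_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  per <- floor(params$genome_length / params$n_refs)
  if (per < 1) stop("genome_length too small for n_refs")
  chars <- lapply(seq_len(params$n_refs), function(i)
    sample(c("A", "C", "G", "T"), per, replace = TRUE))
  rep_info <- data.table(family = integer(0), copy = integer(0),
                         ref_id = integer(0), start = integer(0),
                         end = integer(0))
  rp <- params$repeats
  if (!is.null(rp)) {
    fam <- as.integer(rp$families %||% 1L)
    cnt <- as.integer(rp$count)
    len <- as.integer(rp$length)
    div <- rp$divergence %||% 0
    if (fam * cnt * len > 0.8 * params$genome_length)
      stop("repeat specification exceeds the genome length")
    placed <- lapply(seq_len(params$n_refs), function(i) integer(0))
    for (f in seq_len(fam)) {
      consensus <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      for (cp in seq_len(cnt)) {
        for (try in 1:200) {
          r <- sample.int(params$n_refs, 1L)
          if (per < len + 2L) stop("repeat length exceeds reference length")
          s <- sample.int(per - len + 1L, 1L)  # 1-based start
          if (!any(abs(placed[[r]] - s) < len)) break
          if (try == 200) stop("could not place repeats without overlap")
        }
        placed[[r]] <- c(placed[[r]], s)
        # copy 1 is the consensus itself; later copies diverge at rate `div`
        chars[[r]][s:(s + len - 1L)] <-
          if (cp == 1L) consensus else .mutate_chars(consensus, div)
        rep_info <- rbind(rep_info,
                          data.table(family = f, copy = cp, ref_id = r - 1L,
                                     start = s - 1L, end = s - 1L + len))
      }
    }
  }
  if (params$n_gaps > 0L && params$n_gap_length > 0L) {
    for (g in seq_len(params$n_gaps)) {
      r <- sample.int(params$n_refs, 1L)
      s <- sample.int(per - params$n_gap_length + 1L, 1L)
      chars[[r]][s:(s + params$n_gap_length - 1L)] <- "N"
    }
  }
  seqs <- vapply(chars, paste, character(1), collapse = "")
  names(seqs) <- sprintf("ref%d", seq_len(params$n_refs))
  list(refs = reference_set(seqs), repeat_info = rep_info[])
}

#' Simulate barcoded paired-end reads with ground truth
#'
#' Fragments are sampled uniformly over the references proportional to
#' length; mates of `read_length` bases are taken FR-oriented from the
#' fragment ends (the sequenced strand is random, so mate 1 is forward for
#' about half the pairs); substitutions are i.i.d. at
#' `substitution_rate`; barcodes are drawn uniformly from a generated
#' permit list with single-base errors injected at `barcode_error_rate`;
#' a `duplicate_rate` fraction of fragments is emitted twice.
#' Deterministic under `params$seed + 1`.
#'
#' @param genome a [make_genome()] result (or a [reference_set()]).
#' @param params a [sim_params()].
#' @return list of class `sim_reads`: `r1`, `r2`, `r3` (named character
#'   vectors in 10x scATAC layout: genomic mate 1, barcode read, genomic
#'   mate 2), `truth` (`data.table` with `pair_id`, `barcode` (true),
#'   `ref_id`, `ref`, `start`, `end`, `ori1`, `is_dup`), and `permit`.
#' @export
simulate_pairs <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  refs <- if (inherits(genome, "reference_set")) genome else genome$refs
  set.seed(params$seed + 1L)
  rl <- params$read_length
  permit <- character(0)
  while (length(permit) < params$barcode_n)
    permit <- unique(c(permit, replicate(params$barcode_n, .rand_seq(params$barcode_length))))
  permit <- permit_list(permit[seq_len(params$barcode_n)])

  n <- params$n_pairs
  L <- refs$L
  if (params$fragment_mean + 4 * params$fragment_sd >= min(L))
    stop("fragment length distribution too wide for the references")
  ref_id <- sample.int(length(L), n, replace = TRUE, prob = L) - 1L
  flen <- pmax(rl, as.integer(round(rnorm(n, params$fragment_mean,
                                          params$fragment_sd))))
  flen <- pmin(flen, L[ref_id + 1L])
  start <- vapply(seq_len(n), function(i)
    sample.int(L[ref_id[i] + 1L] - flen[i] + 1L, 1L) - 1L, integer(1))
  end <- start + flen
  bc_true <- sample(as.character(permit), n, replace = TRUE)
  strand1 <- sample(c("f", "r"), n, replace = TRUE)

  dup <- runif(n) < params$duplicate_rate
  idx <- c(seq_len(n), which(dup))
  is_dup <- c(rep(FALSE, n), rep(TRUE, sum(dup)))
  ref_id <- ref_id[idx]; start <- start[idx]; end <- end[idx]
  bc_true <- bc_true[idx]; strand1 <- strand1[idx]
  m <- length(idx)
  pair_id <- sprintf("p%06d", seq_len(m))

  left <- substring(refs$seqs[ref_id + 1L], start + 1L, start + rl)
  right <- revcomp(substring(refs$seqs[ref_id + 1L], end - rl + 1L, end))
  r1 <- ifelse(strand1 == "f", left, right)
  r3 <- ifelse(strand1 == "f", right, left)

  r1 <- .add_subs(r1, params$substitution_rate)
  r3 <- .add_subs(r3, params$substitution_rate)

  bc_obs <- bc_true
  bce <- which(runif(m) < params$barcode_error_rate)
  if (length(bce)) {
    pos <- sample.int(params$barcode_length, length(bce), replace = TRUE)
    for (j in seq_along(bce)) {
      i <- bce[j]
      ch <- substr(bc_obs[i], pos[j], pos[j])
      repl <- sample(setdiff(c("A", "C", "G", "T"), ch), 1L)
      substr(bc_obs[i], pos[j], pos[j]) <- repl
    }
  }

  names(r1) <- names(r3) <- pair_id
  r2 <- stats::setNames(bc_obs, pair_id)
  truth <- data.table(pair_id = pair_id, barcode = bc_true,
                      ref_id = ref_id, ref = refs$names[ref_id + 1L],
                      start = start, end = end, ori1 = strand1,
                      is_dup = is_dup)
  structure(list(r1 = r1, r2 = r2, r3 = r3, truth = truth, permit = permit),
            class = "sim_reads")
}

# i.i.d. substitutions at `rate`, vectorized over reads
.add_subs <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0L)) {
    ch <- strsplit(reads[i], "")[[1L]]
    pos <- sample.int(length(ch), nerr[i])
    alt <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    ch[pos] <- alt
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Write simulated reads and metadata to disk
#'
#' Emits the 10x scATAC layout: `R1.fastq` (genomic mate 1), `R2.fastq`
#' (barcode read), `R3.fastq` (genomic mate 2), plus `genome.fa`,
#' `permit.txt` and `truth.tsv`.
#'
#' @param sim a [simulate_pairs()] result.
#' @param dir output directory (created if needed).
#' @param refs optional [reference_set()] to write as `genome.fa`.
#' @param gzip gzip the FASTQ files.
#' @return named character vector of the written paths.
#' @export
write_sim_reads <- function(sim, dir, refs = NULL, gzip = FALSE) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- c(R1 = file.path(dir, paste0("R1", ext)),
             R2 = file.path(dir, paste0("R2", ext)),
             R3 = file.path(dir, paste0("R3", ext)),
             permit = file.path(dir, "permit.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_fastq <- function(reads, path) {
    con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    qual <- vapply(nchar(reads), function(l)
      paste(rep("I", l), collapse = ""), character(1))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  }
  write_fastq(sim$r1, paths[["R1"]])
  write_fastq(sim$r2, paths[["R2"]])
  write_fastq(sim$r3, paths[["R3"]])
  writeLines(as.character(sim$permit), paths[["permit"]])
  fwrite(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE)
  if (!is.null(refs)) {
    paths <- c(paths, genome = file.path(dir, "genome.fa"))
    write_fasta(refs, paths[["genome"]])
  }
  paths
}

#' Score mapped fragments against the simulation truth
#'
#' Joins fragments to truth by read id; a pair is correct when the
#' reported reference matches and both interval ends are within
#' `tolerance` bases of the truth.
#'
#' @param fragments `map_pairs()$fragments` (or a fragment TSV path).
#' @param truth the `truth` table from [simulate_pairs()].
#' @param tolerance positional slack in bases (default 0).
#' @param stats optional `map_pairs()$stats` for unmapped/multimapped
#'   counts.
#' @return list of class `accuracy_report`: `total`, `mapped`, `correct`,
#'   `accuracy`, `mapping_rate`, `multimapped`, `unmapped`,
#'   `n_unmatched_ids`.
#' @export
evaluate_mapping <- function(fragments, truth, tolerance = 0L, stats = NULL) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  fragments <- as.data.table(fragments)
  truth <- as.data.table(truth)
  j <- merge(fragments, truth[, .(pair_id, true_ref = ref_id,
                                  true_start = start, true_end = end)],
             by.x = "read_id", by.y = "pair_id", all.x = TRUE)
  unmatched <- sum(is.na(j$true_start))
  ok <- !is.na(j$true_start) & j$ref_id == j$true_ref &
    abs(j$start - j$true_start) <= tolerance &
    abs(j$end - j$true_end) <= tolerance
  total <- nrow(truth)
  mapped <- nrow(fragments)
  structure(list(total = total, mapped = mapped, correct = sum(ok),
                 accuracy = sum(ok) / total, mapping_rate = mapped / total,
                 multimapped = stats$multimapped %||% NA_integer_,
                 unmapped = stats$unmapped %||% NA_integer_,
                 n_unmatched_ids = unmatched),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy_report: %d pairs; mapped %d (%.2f%%), ",
                     "correct %d (accuracy %.4f)\n"),
              x$total, x$mapped, 100 * x$mapping_rate, x$correct,
              x$accuracy))
  invisible(x)
}

#' Score a deduplicated BED against the simulation truth
#'
#' BED-level evaluation joins on barcode and interval rather than read id:
#' a truth fragment is recovered when a BED record with the same
#' reference, the same (corrected) barcode, and both interval ends within
#' `tolerance` exists.
#'
#' @param bed a [dedup_fragments()] result (or BED path).
#' @param truth the `truth` table from [simulate_pairs()].
#' @param tolerance positional slack in bases.
#' @return list with `total`, `recovered` and `recovery_rate`.
#' @export
evaluate_bed <- function(bed, truth, tolerance = 0L) {
  if (is.character(bed)) bed <- read_bed(bed)
  bed <- as.data.table(bed)
  truth <- as.data.table(truth)
  if (tolerance == 0L) {
    hit <- truth[, paste(ref, start, end, barcode)] %in%
      bed[, paste(chrom, start, end, barcode)]
  } else {
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      t <- truth[i]
      nrow(bed[chrom == t$ref & barcode == t$barcode &
                 abs(start - t$start) <= tolerance &
                 abs(end - t$end) <= tolerance]) > 0L
    }, logical(1))
  }
  list(total = nrow(truth), recovered = sum(hit),
       recovery_rate = sum(hit) / nrow(truth))
}
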