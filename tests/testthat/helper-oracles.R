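# Toy-transcriptome builders and independent oracle implementations used
# across the suite. Oracles deliberately use different algorithms from the
# package code paths they check.

# build a transcriptome from compact per-transcript exon lists
toy_tx <- function(..., chrom = "chr1", strand = "+", gene = "g1") {
  txs <- list(...)
  rows <- lapply(names(txs), function(id) {
    m <- txs[[id]]
    data.frame(chrom = chrom, start = m[, 1], end = m[, 2], strand = strand,
               transcript_id = id, gene_id = gene,
               stringsAsFactors = FALSE)
  })
  transcriptome(do.call(rbind, rows))
}

ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# write a genome FASTA with one chromosome and return a genome_seq
toy_genome <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), f)
  read_genome(f)
}

# brute-force support filter: explicit loop over samples
oracle_support <- function(counts, min_reads, min_samples) {
  n <- 0L
  for (cc in counts) if (cc >= min_reads) n <- n + 1L
  n >= min_samples
}

# independent PWM scorer: per-position loop with explicit bounds search
oracle_pwm_score <- function(seq, pwm) {
  bases <- c("A", "C", "G", "T")
  m <- unclass(pwm)
  raw <- 0; lo <- 0; hi <- 0
  ch <- strsplit(seq, "")[[1]]
  for (p in 1:13) {
    v <- log2(m[p, ] / 0.25)
    raw <- raw + v[[match(ch[p], bases)]]
    lo <- lo + min(v)
    hi <- hi + max(v)
  }
  100 * (raw - lo) / (hi - lo)
}

# exhaustive all-ATG anchor oracle: translate from every ATG of every
# transcript of the gene with substring arithmetic
oracle_anchor <- function(seqs) {
  best_len <- -1L
  best_id <- NA_character_
  best_start <- NA_integer_
  for (id in sort(names(seqs))) {
    s <- seqs[[id]]
    n <- nchar(s)
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    tx_best <- NULL
    for (a in as.integer(hits)) {
      len <- 0L
      p <- a
      repeat {
        if (p + 2L > n) break
        cod <- substr(s, p, p + 2L)
        len <- len + 3L
        if (cod %in% c("TAA", "TAG", "TGA")) break
        p <- p + 3L
      }
      if (is.null(tx_best) || len > tx_best$len)
        tx_best <- list(start = a, len = len)
    }
    if (!is.null(tx_best) && tx_best$len > best_len) {
      best_len <- tx_best$len
      best_id <- id
      best_start <- tx_best$start
    }
  }
  if (best_len < 0) return(NULL)
  list(transcript = best_id, start = best_start, length = best_len)
}

# small simulated data set reused by several test files
small_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      dir <- file.path(tempdir(), "rtdkit-small-sim")
      memo <<- simulate_rtd(fixture_spec(seed = 42L, n_genes = 24L,
                                         n_samples = 6L), dir)
    }
    memo
  }
})
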