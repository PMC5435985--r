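test_that("padding extends every isoform to the gene's longest region", {
  chr <- strrep("ACGT", 300)
  g <- toy_genome(list(chr1 = chr))
  tx <- toy_tx(long = ex(100, 300, 401, 900),
               short = ex(150, 300, 401, 850))
  out <- pad_transcriptome(tx, g)
  sp <- genomic_spans(out)
  expect_equal(GenomicRanges::start(sp), c(100, 100))
  expect_equal(GenomicRanges::end(sp), c(900, 900))
  # intron chains unchanged, no new junctions
  expect_identical(unname(intron_chain_keys(out)),
                   unname(intron_chain_keys(tx)))
  adj <- attr(out, "adjustments")
  expect_equal(adj$added_5p[adj$transcript_id == "short"], 50)
  expect_equal(adj$added_3p[adj$transcript_id == "short"], 50)
  # single-transcript gene is a fixed point
  one <- toy_tx(t1 = ex(10, 50, 101, 200))
  expect_equal(as.data.frame(pad_transcriptome(one, g)$exons),
               as.data.frame(one$exons))
})

test_that("padding through a terminal intron yields an IR-like end", {
  chr <- strrep("ACGT", 300)
  g <- toy_genome(list(chr1 = chr))
  tx <- toy_tx(full = ex(100, 200, 301, 400, 501, 600),
               stub = ex(100, 200, 301, 450))   # ends inside 3'UTR intron
  out <- pad_transcriptome(tx, g)
  grl <- exons_by_transcript(out)
  # the stub's last exon runs straight through to the common end
  expect_equal(GenomicRanges::end(grl[["stub"]])[2], 600)
  expect_equal(length(grl[["stub"]]), 2)
})

test_that("padded sequences contain the originals as contiguous substrings", {
  sim <- small_sim()
  g <- read_genome(sim$files$genome)
  tx <- read_gtf(sim$files$assembly_gtf)
  q <- build_quasi(tx, g)
  # per-gene uniform spans
  sp <- genomic_spans(q)
  df <- data.frame(g = S4Vectors::mcols(sp)$gene_id,
                   s = GenomicRanges::start(sp),
                   e = GenomicRanges::end(sp))
  expect_true(all(tapply(df$s, df$g, function(z) length(unique(z))) == 1))
  expect_true(all(tapply(df$e, df$g, function(z) length(unique(z))) == 1))
  before <- as.character(extract_sequences(tx, g))
  after <- as.character(extract_sequences(q, g))
  expect_true(all(mapply(grepl, before, after[names(before)],
                         fixed = TRUE)))
  expect_true(all(nchar(after[names(before)]) >= nchar(before)))
  # idempotence
  q2 <- build_quasi(q, g)
  expect_equal(as.data.frame(q2$exons), as.data.frame(q$exons))
})

test_that("trimming clips to the shortest region and drops outside exons", {
  tx <- toy_tx(long = ex(100, 300, 401, 900),
               short = ex(150, 300, 401, 850))
  out <- trim_transcriptome(tx)
  sp <- genomic_spans(out)
  expect_equal(GenomicRanges::start(sp), c(150, 150))
  expect_equal(GenomicRanges::end(sp), c(850, 850))
  # trim point inside a 5'UTR intron: the longer transcript loses exon 1
  tx2 <- toy_tx(long = ex(100, 200, 301, 400, 501, 900),
                short = ex(250, 400, 501, 900))
  out2 <- trim_transcriptome(tx2)
  grl <- exons_by_transcript(out2)
  expect_equal(length(grl[["long"]]), 2)
  expect_equal(GenomicRanges::start(grl[["long"]])[1], 301)
  # trimmed sequences are substrings of the originals
  chr <- strrep("TGCA", 300)
  g <- toy_genome(list(chr1 = chr))
  before <- as.character(extract_sequences(tx2, g))
  after <- as.character(extract_sequences(out2, g))
  expect_true(all(mapply(grepl, after, before[names(after)], fixed = TRUE)))
  # single-transcript gene: pad(trim(x)) is the identity
  one <- toy_tx(t1 = ex(10, 50, 101, 200))
  expect_equal(as.data.frame(pad_transcriptome(trim_transcriptome(one),
                                               g)$exons),
               as.data.frame(one$exons))
})

test_that("empty trim windows are skipped with a warning", {
  tx <- transcriptome(rbind(
    data.frame(chrom = "chr1", start = 100, end = 200, strand = "+",
               transcript_id = "a", gene_id = "g1"),
    data.frame(chrom = "chr1", start = 300, end = 400, strand = "+",
               transcript_id = "b", gene_id = "g1")))
  expect_warning(out <- trim_transcriptome(tx), "empty trim window")
  expect_equal(as.data.frame(out$exons), as.data.frame(tx$exons))
})

test_that("transcript sequence extraction splices exons strand-aware", {
  g <- toy_genome(list(chr1 = "ACGTTTGCA"))
  plus <- toy_tx(t1 = ex(1, 3, 7, 9))
  expect_equal(as.character(extract_sequences(plus, g))[["t1"]], "ACGGCA")
  minus <- toy_tx(t1 = ex(1, 3, 7, 9), strand = "-")
  expect_equal(as.character(extract_sequences(minus, g))[["t1"]], "TGCCGT")
  mono <- toy_tx(t1 = ex(2, 5))
  expect_equal(as.character(extract_sequences(mono, g))[["t1"]], "CGTT")
})
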