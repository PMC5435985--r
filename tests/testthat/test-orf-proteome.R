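test_that("longest ORF scanning walks codons from every ATG", {
  o <- longest_orf("AAATGGCTTAAGG")
  expect_equal(o$start, 3)
  expect_equal(o$length, 9)          # ATG GCT TAA
  expect_false(o$ran_off_end)
  o2 <- longest_orf("GGATGAAATAG")
  expect_equal(o2$start, 3)
  expect_equal(o2$length, 9)         # ATG AAA TAG
  expect_null(longest_orf("GGCCCGGC"))
  # two equal-length ORFs: the 5'-most ATG wins
  o3 <- longest_orf("ATGAAATAACCATGAAATAA")
  expect_equal(o3$start, 1)
  # no in-frame stop: translated to the last complete codon
  o4 <- longest_orf("ATGAAAA")
  expect_equal(o4$length, 6)
  expect_true(o4$ran_off_end)
})

test_that("fallback translation gives the longest-ORF protein", {
  r <- translate_fallback("GGATGAAATAG")
  expect_equal(r$protein, "MK")
  expect_equal(r$stop_status, "stop_found")
  expect_null(translate_fallback("CCCCCC"))
})

test_that("anchor selection matches the exhaustive all-ATG oracle", {
  # hand case: anchor comes from the transcript with the longest ORF
  g <- toy_genome(list(chr1 = paste0(
    strrep("C", 10), "ATG", strrep("GCT", 30), "TAA", strrep("C", 40))))
  tx <- transcriptome(rbind(
    data.frame(chrom = "chr1", start = 1, end = 110, strand = "+",
               transcript_id = "t1", gene_id = "g1"),
    data.frame(chrom = "chr1", start = 60, end = 146, strand = "+",
               transcript_id = "t2", gene_id = "g1")))
  a <- select_anchor(tx, g)
  expect_equal(a$anchor_transcript, "t1")
  expect_equal(a$aug_pos1, 11)
  # simulated genes: oracle equality transcript by transcript
  sim <- small_sim()
  gg <- read_genome(sim$files$genome)
  rtd <- read_gtf(sim$files$reference_gtf)
  anchors <- select_anchor(rtd, gg)
  seqs <- as.character(extract_sequences(rtd, gg))
  t2g <- tx2gene(rtd)
  for (i in seq_len(nrow(anchors))) {
    ids <- t2g$transcript_id[t2g$gene_id == anchors$gene_id[i]]
    want <- oracle_anchor(as.list(seqs[ids]))
    expect_equal(anchors$anchor_transcript[i], want$transcript)
    expect_equal(anchors$orf_length[i], want$length)
  }
})

test_that("anchored translation maps the AUG splice-aware, with fallback", {
  # gene: exon1 carries the anchor AUG; t2 lost that exon via AS
  chr <- paste0(strrep("C", 10),
                "ATGGCTGCTGCT",          # exon1: 11..22 (AUG at 11)
                strrep("T", 20),         # intron
                "GCAGCAGCATAA",          # exon2: 43..54
                strrep("C", 10),
                "ATGAAATAG",             # exon3: 65..73 (fallback ORF)
                strrep("C", 10))
  g <- toy_genome(list(chr1 = chr))
  tx <- transcriptome(rbind(
    data.frame(chrom = "chr1", start = c(11, 43), end = c(22, 54),
               strand = "+", transcript_id = "t1", gene_id = "g1"),
    data.frame(chrom = "chr1", start = c(43, 65), end = c(54, 73),
               strand = "+", transcript_id = "t2", gene_id = "g1")))
  tr <- translate_transcriptome(tx, g)
  rec <- tr$records
  expect_equal(rec$mode[rec$transcript_id == "t1"], "anchored")
  expect_equal(rec$mode[rec$transcript_id == "t2"], "fallback_longest_orf")
  expect_equal(as.character(tr$proteins[["t1"]]), "MAAAAAA")
  expect_equal(as.character(tr$proteins[["t2"]]), "MK")
  # every translated protein starts with M
  expect_true(all(substr(as.character(tr$proteins), 1, 1) == "M"))
  # the anchor transcript's anchored translation equals its longest ORF
  seqs <- as.character(extract_sequences(tx, g))
  o <- longest_orf(seqs[["t1"]])
  expect_equal(nchar(as.character(tr$proteins[["t1"]])),
               o$length / 3 - 1)
})

test_that("trypsin digestion cleaves after K/R except before P", {
  expect_equal(digest_trypsin("MKAYLDRPQSTVKLMNPR")[[1]], "AYLDRPQSTVK")
  expect_equal(digest_trypsin("MAYLDQSTV")[[1]], "MAYLDQSTV")
  expect_equal(digest_trypsin("KPKPKPKPKP")[[1]], "KPKPKPKPKP")
  # reconstruction: fragments (no length filter) concatenate to the protein
  set.seed(3)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    p <- paste(sample(aa, sample(20:200, 1), TRUE), collapse = "")
    frags <- digest_trypsin(p, min_len = 1)[[1]]
    expect_equal(paste(frags, collapse = ""), p)
    # no internal K/R followed by non-P
    internal <- unlist(lapply(frags, function(f)
      if (nchar(f) > 1) substring(f, 1:(nchar(f) - 1), 1:(nchar(f) - 1))))
    nxt <- unlist(lapply(frags, function(f)
      if (nchar(f) > 1) substring(f, 2:nchar(f), 2:nchar(f))))
    bad <- internal %in% c("K", "R") & nxt != "P"
    expect_false(any(bad))
  }
  expect_warning(digest_trypsin("MKXXXXXXXXR"), "non-standard")
})

test_that("the peptide index flags isoform-unique peptides", {
  p1 <- "MAAAAAAKGGGGGGGKCCCCCCC"
  idx <- build_peptide_index(digest_trypsin(list(t1 = p1, t2 = p1)))
  expect_equal(idx$summary$n_unique, 0)
  p2 <- "MAAAAAAKWWWWWWWKCCCCCCC"   # middle peptide differs
  idx2 <- build_peptide_index(
    digest_trypsin(list(t1 = p1, t2 = p2)),
    tx2gene = data.frame(transcript_id = c("t1", "t2"),
                         gene_id = c("g1", "g1")))
  expect_equal(idx2$summary$n_peptides, 4)
  expect_equal(idx2$summary$n_unique, 2)
  expect_equal(idx2$summary$frac_unique, 0.5)
  expect_equal(idx2$summary$n_transcripts_with_unique, 2)
  expect_equal(idx2$summary$n_genes_with_unique, 1)
  shared <- idx2$index[!idx2$index$unique, ]
  expect_true(all(shared$n_transcripts == 2))
})
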