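test_that("junction filter keeps transcripts with fully supported chains", {
  tx <- toy_tx(good = ex(1, 10, 21, 30, 41, 50),
               bad = ex(1, 10, 21, 30, 45, 60),
               mono = ex(100, 300))
  passing <- c("chr1:+:11-20", "chr1:+:31-40")
  rep <- filter_by_junctions(tx, passing)
  expect_setequal(rep$kept, c("good", "mono"))
  expect_equal(rep$removed$reason, "unsupported_junction")
  # reasons distinguish non-canonical junctions when the table is given
  jdf <- data.frame(junction_key = c("chr1:+:11-20", "chr1:+:31-40",
                                     "chr1:+:31-44"),
                    pass = c(TRUE, TRUE, FALSE),
                    canonical = c(TRUE, TRUE, FALSE))
  rep2 <- filter_by_junctions(tx, jdf)
  expect_equal(rep2$removed$reason[rep2$removed$transcript_id == "bad"],
               "non_canonical_junction")
  # kept transcripts only use passing junctions
  kept_tx <- apply_filter(tx, rep)
  expect_true(all(introns_df(kept_tx)$junction_key %in% passing))
})

test_that("antisense filter removes only fully contained opposite-strand transcripts", {
  reference <- toy_tx(r1 = ex(1000, 1200, 1500, 2000), gene = "REF1")
  contained <- toy_tx(a = ex(1100, 1300, 1600, 1900), strand = "-",
                      gene = "x1")
  extending <- toy_tx(b = ex(1100, 1300, 1600, 2300), strand = "-",
                      gene = "x2")
  same <- toy_tx(c = ex(1100, 1900), strand = "+", gene = "x3")
  tx <- transcriptome(c(contained$exons, extending$exons, same$exons))
  rep <- filter_antisense(tx, reference)
  expect_equal(rep$removed$transcript_id, "a")
  expect_equal(rep$removed$reason, "antisense_contained")
  expect_setequal(rep$kept, c("b", "c"))
})

test_that("unknown-gene filter removes novel loci but rescues by exon overlap", {
  reference <- toy_tx(r1 = ex(1000, 1200, 1500, 2000), gene = "REF1")
  known <- toy_tx(k = ex(1000, 1200), gene = "REF1")
  rescue <- toy_tx(n = ex(1100, 1250), gene = "NOV1")
  orphan <- toy_tx(o = ex(5000, 5400), gene = "NOV2")
  tx <- transcriptome(c(known$exons, rescue$exons, orphan$exons))
  rep <- filter_unknown_genes(tx, reference)
  expect_setequal(rep$kept, c("k", "n"))
  expect_equal(rep$removed$transcript_id, "o")
  expect_equal(unname(rep$reassigned["n"]), "REF1")
  out <- apply_filter(tx, rep)
  expect_equal(tx2gene(out)$gene_id[tx2gene(out)$transcript_id == "n"],
               "REF1")
  # opposite-strand overlap does not rescue
  anti <- toy_tx(z = ex(1100, 1250), strand = "-", gene = "NOV3")
  rep2 <- filter_unknown_genes(anti, reference)
  expect_equal(rep2$removed$transcript_id, "z")
})

test_that("expression filter requires TPM strictly above 1 in 3 samples", {
  tx <- toy_tx(a = ex(1, 100), b = ex(201, 300), c = ex(401, 500),
               d = ex(601, 700))
  tpm <- rbind(a = c(1.5, 2.0, 1.2, 0.1),
               b = c(5.0, 0.2, 0.3, 0.0),
               c = c(0, 0, 0, 0),
               d = c(1.0, 1.0, 1.0, 1.0))  # exactly 1 never qualifies
  colnames(tpm) <- paste0("s", 1:4)
  rep <- filter_low_expression(tx, tpm)
  expect_equal(rep$kept, "a")
  expect_setequal(rep$removed$transcript_id, c("b", "c", "d"))
  # a transcript absent from the table is removed with a warning
  tx2 <- toy_tx(a = ex(1, 100), zz = ex(900, 999))
  expect_warning(rep2 <- filter_low_expression(tx2, tpm), "absent")
  expect_true("zz" %in% rep2$removed$transcript_id)
})

test_that("each filter is idempotent on its own kept set", {
  sim <- small_sim()
  g <- read_genome(sim$files$genome)
  asm <- read_gtf(sim$files$assembly_gtf)
  ref <- read_gtf(sim$files$reference_gtf)
  sj <- pool_junctions(mapply(read_sj_tab, sim$files$sj, sim$samples,
                              SIMPLIFY = FALSE))
  jdf <- passing_junctions(sj, g)
  tpm <- read_quant(sim$files$quant, sim$samples)
  filters <- list(
    function(t) filter_by_junctions(t, jdf),
    function(t) filter_antisense(t, ref),
    function(t) filter_unknown_genes(t, ref),
    function(t) filter_low_expression(t, tpm))
  for (f in filters) {
    r1 <- f(asm)
    kept <- apply_filter(asm, r1)
    r2 <- f(kept)
    expect_equal(nrow(r2$removed), 0)
  }
})
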