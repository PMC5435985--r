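test_that("redundancy removal keeps the longest-span chain representative", {
  tx <- toy_tx(short = ex(150, 300, 401, 850),
               long = ex(100, 300, 401, 900),
               other = ex(100, 300, 402, 900))
  out <- remove_redundant(tx)
  expect_setequal(transcript_ids(out), c("long", "other"))
  dropped <- attr(out, "removed_redundant")
  expect_equal(dropped$transcript_id, "short")
  expect_equal(dropped$kept_as, "long")
  # byte-identical transcripts collapse to one (lexicographic tie-break)
  tx2 <- toy_tx(b = ex(1, 10, 21, 30), a = ex(1, 10, 21, 30))
  out2 <- remove_redundant(tx2)
  expect_equal(transcript_ids(out2), "a")
})

test_that("mono-exonic transcripts are redundant only on identical spans", {
  tx <- toy_tx(m1 = ex(100, 500), m2 = ex(100, 500), m3 = ex(100, 400))
  out <- remove_redundant(tx)
  expect_setequal(transcript_ids(out), c("m1", "m3"))
})

test_that("merge adds novel chains and prefers the base representative", {
  base <- toy_tx(b1 = ex(100, 300, 401, 900))
  incoming <- transcriptome(c(
    toy_tx(i1 = ex(150, 300, 401, 850))$exons,          # same chain, shorter
    toy_tx(i2 = ex(100, 300, 450, 900))$exons,          # novel chain
    toy_tx(i3 = ex(50, 300, 401, 900))$exons))          # same chain, longer
  out <- merge_step(base, incoming)
  expect_setequal(transcript_ids(out), c("i3", "i2"))
  # equal spans: base representative wins
  out2 <- merge_step(base, toy_tx(i4 = ex(100, 300, 401, 900)))
  expect_equal(transcript_ids(out2), "b1")
  # disjoint gene sets: plain union
  far <- toy_tx(f1 = ex(5000, 5200, 5301, 5600), gene = "g9")
  out3 <- merge_step(base, far)
  expect_setequal(transcript_ids(out3), c("b1", "f1"))
})

test_that("merge reconciles incoming gene ids by same-strand exon overlap", {
  base <- toy_tx(b1 = ex(100, 300, 401, 900), gene = "gBase")
  incoming <- toy_tx(i1 = ex(100, 300, 450, 900), gene = "gAsm")
  out <- merge_step(base, incoming)
  t2g <- tx2gene(out)
  expect_equal(unique(t2g$gene_id), "gBase")
})

test_that("merge plans fold left with chain-set conservation", {
  sim <- small_sim()
  asm <- read_gtf(sim$files$assembly_gtf)
  # single-input plan is just redundancy removal
  one <- run_merge_plan(list(asm))
  expect_setequal(transcript_ids(one$transcriptome),
                  transcript_ids(remove_redundant(asm)))
  # split the assembly in two and merge; the chain set must be conserved
  ids <- transcript_ids(asm)
  half <- seq_len(length(ids) %/% 2)
  t1 <- subset_transcripts(asm, ids[half])
  t2 <- subset_transcripts(asm, ids[-half])
  merged <- run_merge_plan(list(t1, t2), labels = c("a", "b"))$transcriptome
  want_chains <- unique(intron_chain_keys(remove_redundant(asm)))
  got_chains <- unique(intron_chain_keys(merged))
  expect_setequal(got_chains, want_chains)
  # merge order leaves the chain set invariant
  swapped <- run_merge_plan(list(t2, t1), labels = c("b", "a"))$transcriptome
  expect_setequal(unique(intron_chain_keys(swapped)), want_chains)
  # no gene keeps two multi-exon transcripts with one chain
  keys <- intron_chain_keys(merged)
  t2g <- tx2gene(merged)
  nex <- lengths(exons_by_transcript(merged))
  multi <- names(nex)[nex > 1]
  combo <- paste(t2g$gene_id[match(multi, t2g$transcript_id)], keys[multi])
  expect_false(anyDuplicated(combo) > 0)
  # chain-set idempotence: merging the result with itself changes nothing
  again <- merge_step(merged, merged)
  expect_setequal(transcript_ids(again), transcript_ids(merged))
})
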