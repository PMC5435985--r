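test_that("pairwise comparison classifies IR, Alt5, Alt3 and ES", {
  # IR: t_ir retains the intron 201..300
  tx <- toy_tx(fs = ex(101, 200, 301, 400, 501, 600),
               t_ir = ex(101, 400, 501, 600),
               t_alt5 = ex(101, 212, 301, 400, 501, 600),
               t_alt3 = ex(101, 200, 289, 400, 501, 600),
               t_es = ex(101, 200, 501, 600))
  ir <- detect_events_pairwise(tx, "fs", "t_ir")
  expect_equal(ir$type, "IR")
  expect_equal(c(ir$start, ir$end), c(201, 300))
  expect_equal(ir$as_id, "t_ir")
  expect_equal(ir$fs_id, "fs")
  a5 <- detect_events_pairwise(tx, "fs", "t_alt5")
  expect_equal(a5$type, "Alt5")
  expect_equal(c(a5$start, a5$end), c(201, 212))
  expect_equal(a5$as_id, "t_alt5")
  a3 <- detect_events_pairwise(tx, "fs", "t_alt3")
  expect_equal(a3$type, "Alt3")
  expect_equal(c(a3$start, a3$end), c(289, 300))
  expect_equal(a3$as_id, "t_alt3")
  es <- detect_events_pairwise(tx, "fs", "t_es")
  expect_equal(es$type, "ES")
  expect_equal(c(es$start, es$end), c(301, 400))
  expect_equal(es$as_id, "t_es")
  # identical structures: no events
  tx2 <- toy_tx(a = ex(1, 10, 21, 30), b = ex(1, 10, 21, 30))
  expect_equal(nrow(detect_events_pairwise(tx2, "a", "b")), 0)
})

test_that("pairwise detection is symmetric and strand-mirrored", {
  tx <- toy_tx(fs = ex(101, 200, 301, 400, 501, 600),
               t_ir = ex(101, 400, 501, 600),
               t_alt5 = ex(101, 212, 301, 400, 501, 600))
  for (pair in list(c("fs", "t_ir"), c("fs", "t_alt5"))) {
    e1 <- detect_events_pairwise(tx, pair[1], pair[2])
    e2 <- detect_events_pairwise(tx, pair[2], pair[1])
    expect_equal(e1[, c("type", "start", "end", "as_id", "fs_id")],
                 e2[, c("type", "start", "end", "as_id", "fs_id")])
  }
  # mirroring the gene onto the minus strand swaps Alt5 and Alt3
  minus <- toy_tx(fs = ex(101, 200, 301, 400, 501, 600),
                  t_alt = ex(101, 212, 301, 400, 501, 600),
                  strand = "-")
  ev <- detect_events_pairwise(minus, "fs", "t_alt")
  expect_equal(ev$type, "Alt3")
  expect_equal(ev$as_id, "t_alt")
})

test_that("different genes cannot be compared", {
  tx <- transcriptome(rbind(
    data.frame(chrom = "chr1", start = 1, end = 10, strand = "+",
               transcript_id = "a", gene_id = "g1"),
    data.frame(chrom = "chr1", start = 100, end = 110, strand = "+",
               transcript_id = "b", gene_id = "g2")))
  expect_error(detect_events_pairwise(tx, "a", "b"), "different genes")
})

test_that("TPM splicing ratios sum AS and FS sets per sample", {
  events <- data.frame(event_id = "e1", as_ids = "t2,t3", fs_ids = "t1")
  tpm <- rbind(t1 = c(8, 4, 0), t2 = c(1, 1, 1), t3 = c(1, 1, 1))
  colnames(tpm) <- c("s1", "s2", "s3")
  r <- splicing_ratios(events, tpm)
  expect_equal(r$ratio[r$sample_id == "s1"], 0.25)
  expect_equal(r$ratio[r$sample_id == "s2"], 0.5)
  expect_true(is.na(r$ratio[r$sample_id == "s3"]))
  expect_true(r$undefined[r$sample_id == "s3"])
  # scale invariance: rescaling a sample leaves ratios unchanged
  tpm2 <- tpm
  tpm2[, "s1"] <- tpm2[, "s1"] * 1e3
  r2 <- splicing_ratios(events, tpm2)
  expect_equal(r2$ratio[r2$sample_id == "s1"],
               r$ratio[r$sample_id == "s1"])
  expect_error(splicing_ratios(
    data.frame(event_id = "e2", as_ids = "zz", fs_ids = "t1"), tpm),
    "absent")
})

test_that("peak-area ratios divide each AS product by the FS product", {
  peaks <- data.frame(
    gene_id = "g", event_id = "e1",
    product_label = c("FS", "AS1", "AS2"), sample_id = "s1",
    peak_area = c(4800, 1200, 0))
  r <- splicing_ratios_from_peaks(peaks)
  expect_equal(nrow(r), 2)
  expect_equal(r$ratio[r$product_label == "AS1"], 0.25)
  expect_equal(r$ratio[r$product_label == "AS2"], 0)
  expect_error(splicing_ratios_from_peaks(peaks[-1, ]),
               "exactly one FS row")
})

test_that("concordance reproduces hand-computed correlations", {
  mk <- function(v) data.frame(event_id = paste0("e", seq_along(v)),
                               sample_id = "s1", ratio = v)
  cc <- concordance(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 4)))
  expect_equal(cc$pearson, 1)
  expect_equal(cc$spearman, 1)
  x <- c(0.5, 1, 2, 4, 8)
  cc2 <- concordance(mk(x), mk(x^3))
  expect_equal(cc2$spearman, 1)
  expect_lt(cc2$pearson, 1)
  cc3 <- concordance(mk(c(1, 2, 3, 4)), mk(c(2, 1, 4, 3)))
  expect_equal(cc3$spearman, 0.6)
  expect_equal(cc3$pearson, 0.6)
  expect_equal(cc3$n, 4)
  # affine transforms preserve both correlations
  cc4 <- concordance(mk(x), mk(2.5 * x + 1))
  expect_equal(cc4$pearson, 1)
  expect_equal(cc4$spearman, 1)
  # undefined ratios are excluded pairwise; too few pairs is an error
  a <- mk(c(1, 2, NA, 4))
  b <- mk(c(1, 2, 3, 4))
  expect_equal(concordance(a, b)$n, 3)
  expect_error(concordance(mk(c(1, 2)), mk(c(1, 2))), "at least 3")
})

test_that("aggregated event detection recovers designed events exactly", {
  sim <- small_sim()
  asm <- read_gtf(sim$files$assembly_gtf)
  kept <- subset_transcripts(
    asm, sim$truth$fates$transcript_id[sim$truth$fates$fate == "kept"])
  # put rescued transcripts in their true gene, as the pipeline would
  t2g <- sim$truth$fates
  resc <- t2g[!is.na(t2g$reassigned_to), ]
  ex2 <- kept$exons
  hit <- S4Vectors::mcols(ex2)$transcript_id %in% resc$transcript_id
  S4Vectors::mcols(ex2)$gene_id[hit] <- resc$reassigned_to[
    match(S4Vectors::mcols(ex2)$transcript_id[hit], resc$transcript_id)]
  kept <- transcriptome(ex2)
  got <- detect_events(kept)
  want <- sim$truth$events
  expect_setequal(got$event_id, want$event_id)
  m <- merge(got, want, by = "event_id", suffixes = c("_g", "_w"))
  expect_equal(m$as_ids_g, m$as_ids_w)
  expect_equal(m$fs_ids_g, m$fs_ids_w)
})
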