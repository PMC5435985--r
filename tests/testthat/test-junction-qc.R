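test_that("motif classification recognises the canonical dinucleotide pairs", {
  expect_equal(classify_motif("GT", "AG"), "canonical")
  expect_equal(classify_motif("GC", "AG"), "canonical")
  expect_equal(classify_motif("AT", "AC"), "canonical")
  expect_equal(classify_motif("CT", "AC"), "non_canonical")
  expect_equal(classify_motif("NT", "AG"), "non_canonical")
  expect_equal(classify_motif("gt", "ag"), "canonical")
  expect_error(classify_motif("GX", "AG"), "A,C,G,T,N")
})

test_that("pooling takes the per-sample maximum, never the sum", {
  j <- function(start, sample, n) data.frame(
    chrom = "chr1", start = start, end = start + 99, strand = "+",
    unique_reads = n, multi_reads = 0, sample_id = sample)
  pooled <- pool_junctions(list(j(100, "s1", 12), j(100, "s1", 9)))
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$unique_reads, 12)
  pooled <- pool_junctions(list(j(100, "s1", 12), j(100, "s2", 7)))
  expect_equal(nrow(pooled), 2)
  pooled <- pool_junctions(list(j(100, "s1", 5), j(500, "s1", 6)))
  expect_equal(nrow(pooled), 2)
})

test_that("support filter counts qualifying samples, with oracle agreement", {
  expect_true(support_filter(c(s1 = 12, s2 = 11, s3 = 10, s4 = 0)))
  expect_false(support_filter(c(12, 12, 9)))
  expect_false(support_filter(numeric(0)))
  set.seed(7)
  for (i in 1:50) {
    counts <- rpois(sample(1:10, 1), 12)
    mr <- sample(1:15, 1)
    ms <- sample(1:5, 1)
    expect_identical(support_filter(counts, mr, ms),
                     oracle_support(counts, mr, ms))
  }
})

test_that("passing junctions require canonical motif AND read support", {
  # chr: exon GT..intron..AG exon, one canonical (11..40) and one
  # non-canonical junction (51..80)
  chr <- paste0(strrep("A", 10), "GT", strrep("C", 26), "AG",
                strrep("A", 10), "CT", strrep("C", 26), "AG",
                strrep("A", 10))
  g <- toy_genome(list(chr1 = chr))
  sup <- function(start, end, counts) do.call(rbind, lapply(
    seq_along(counts), function(i) data.frame(
      chrom = "chr1", start = start, end = end, strand = "+",
      unique_reads = counts[i], multi_reads = 0,
      sample_id = paste0("s", i))))
  support <- rbind(sup(11, 40, c(12, 15, 11)),     # canonical + supported
                   sup(51, 80, c(50, 60, 70)),     # non-canonical, strong
                   sup(11, 38, c(12, 11, 0)))      # weak (2 samples >= 10)
  pj <- passing_junctions(support, g)
  keyed <- setNames(pj$pass, pj$junction_key)
  expect_true(keyed[["chr1:+:11-40"]])
  expect_false(keyed[["chr1:+:51-80"]])
  expect_false(keyed[["chr1:+:11-38"]])
  expect_equal(pj$motif[pj$junction_key == "chr1:+:51-80"], "non_canonical")
  # monotonicity: stricter thresholds never add junctions
  for (mr in c(10, 12, 20)) for (ms in c(3, 4)) {
    p2 <- passing_junctions(support, g, min_reads = mr, min_samples = ms)
    expect_true(all(p2$junction_key[p2$pass] %in% pj$junction_key[pj$pass]))
  }
  # undetermined strand can never pass
  s0 <- sup(11, 40, c(50, 50, 50))
  s0$strand <- "*"
  expect_false(any(passing_junctions(s0, g)$pass))
})

test_that("PWMs are built from 13-mers with pseudocounts", {
  m <- build_pwm("CAGGTAAGTATTT", pseudocount = 0)
  expect_equal(unname(m[1, "C"]), 1)
  expect_equal(unname(m[4, "G"]), 1)
  expect_true(all(rowSums(unclass(m)) == 1))
  m2 <- build_pwm("CAGGTAAGTATTT", pseudocount = 0.5)
  expect_true(all(unclass(m2) > 0))
  set.seed(11)
  sites <- vapply(1:4000, function(i)
    paste(sample(c("A", "C", "G", "T"), 13, TRUE), collapse = ""),
    character(1))
  mu <- build_pwm(sites)
  expect_true(all(abs(unclass(mu) - 0.25) < 0.03))
  expect_error(build_pwm("ACGT"), "13-mers")
  expect_error(build_pwm(strrep("X", 13)), "A,C,G,T")
})

test_that("splice-site scores hit 100 on consensus and 0 on anti-consensus", {
  set.seed(5)
  sites <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 13, TRUE,
                 prob = c(.4, .3, .2, .1)), collapse = ""), character(1))
  pwm <- build_pwm(sites)
  bases <- c("A", "C", "G", "T")
  consensus <- paste(bases[apply(unclass(pwm), 1, which.max)],
                     collapse = "")
  anti <- paste(bases[apply(unclass(pwm), 1, which.min)], collapse = "")
  expect_equal(score_splice_site(consensus, pwm), 100)
  expect_equal(score_splice_site(anti, pwm), 0)
  expect_true(is.na(score_splice_site("NAAAAAAAAAAAA", pwm)))
  rnd <- vapply(1:50, function(i)
    paste(sample(bases, 13, TRUE), collapse = ""), character(1))
  got <- score_splice_site(rnd, pwm)
  want <- vapply(rnd, oracle_pwm_score, numeric(1), pwm = pwm,
                 USE.NAMES = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 100))
})

test_that("intron classification applies U12-before-U2 threshold logic", {
  expect_equal(classify_intron_type(50, 50, 80, 70), "U12")
  expect_equal(classify_intron_type(62, 61, 40, 40), "U2")
  expect_equal(classify_intron_type(50, 50, 50, 50), "unclassified")
  # boundary values are strict
  expect_equal(classify_intron_type(60, 60, 75, 65), "unclassified")
  # U12 precedence when both pass
  expect_equal(classify_intron_type(90, 90, 80, 70), "U12")
  expect_equal(classify_intron_type(NA, 90, NA, 70), "unclassified")
})

test_that("PWM TSV serialisation round-trips", {
  m <- default_splice_models()$U2$donor
  f <- tempfile(fileext = ".tsv")
  write_pwm(m, f)
  back <- read_pwm(f, label = "U2")
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("intron scoring on simulated genes finds U2-style splice sites", {
  sim <- small_sim()
  g <- read_genome(sim$files$genome)
  tx <- read_gtf(sim$files$reference_gtf)
  sc <- score_introns(tx, g)
  expect_true(all(sc$u2_donor >= 0 & sc$u2_donor <= 100))
  # consensus-sampled donors should mostly look like U2 sites
  expect_gt(mean(sc$u2_donor > 60), 0.7)
  expect_true(all(sc$intron_type %in% c("U2", "U12", "unclassified")))
})
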