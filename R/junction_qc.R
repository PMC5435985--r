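#' Classify a splice-junction motif
#'
#' A junction is canonical iff its intron-terminal dinucleotides (in
#' transcript orientation) are GT..AG, GC..AG or AT..AC. Any `N` makes the
#' motif non-canonical.
#'
#' @param donor,acceptor Two-letter strings over A, C, G, T, N (vectorised).
#' @return Character vector, `"canonical"` or `"non_canonical"`.
#' @export
classify_motif <- function(donor, acceptor) {
  donor <- toupper(donor)
  acceptor <- toupper(acceptor)
  ok <- grepl("^[ACGTN]{2}$", donor) & grepl("^[ACGTN]{2}$", acceptor)
  if (any(!ok, na.rm = TRUE))
    stop("motif dinucleotides must be 2 letters over {A,C,G,T,N}")
  canon <- paste(donor, acceptor) %in% c("GT AG", "GC AG", "AT AC")
  out <- ifelse(canon, "canonical", "non_canonical")
  out[is.na(donor) | is.na(acceptor)] <- "non_canonical"
  out
}

#' Pool junction records across tables
#'
#' Records for the same junction and sample coming from different tables
#' (e.g. the same reads mapped by two aligners) are collapsed by taking the
#' maximum unique-read count, never the sum: two mappings of the same reads
#' are not independent evidence.
#'
#' @param tables A list of junction record data.frames as returned by
#'   [read_sj_tab()].
#' @return A data.frame with one row per (junction, sample): `chrom`,
#'   `start`, `end`, `strand`, `sample_id`, `unique_reads`, `multi_reads`.
#' @export
pool_junctions <- function(tables) {
  df <- do.call(rbind, tables)
  if (is.null(df) || !nrow(df))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sample_id = character(0), unique_reads = integer(0),
                      multi_reads = integer(0), stringsAsFactors = FALSE))
  key <- paste(df$chrom, df$start, df$end, df$strand, df$sample_id, sep = "\r")
  o <- order(key, -df$unique_reads, -df$multi_reads)
  df <- df[o, ][!duplicated(key[o]), ]
  df <- df[order(df$chrom, df$start, df$end, df$strand, df$sample_id),
           c("chrom", "start", "end", "strand", "sample_id",
             "unique_reads", "multi_reads")]
  rownames(df) <- NULL
  df
}

#' Read-support filter for one junction
#'
#' @param counts Named or unnamed numeric vector of per-sample unique-read
#'   counts for one junction.
#' @param min_reads Minimum unique reads for a sample to count (default 10).
#' @param min_samples Minimum number of qualifying samples (default 3).
#' @return `TRUE` iff at least `min_samples` samples have at least
#'   `min_reads` unique reads.
#' @export
support_filter <- function(counts, min_reads = 10, min_samples = 3) {
  stopifnot(min_reads >= 1, min_samples >= 1)
  sum(counts >= min_reads) >= min_samples
}

#' Motif and support classification of pooled junctions
#'
#' For every distinct junction this extracts the intron-terminal
#' dinucleotides from the genome (strand-aware), classifies the motif, counts
#' supporting samples, and records whether the junction passes both the
#' canonical-motif and the read-support rule. Undetermined-strand junctions
#' cannot be canonical and therefore never pass.
#'
#' @param support Pooled junction table from [pool_junctions()].
#' @param genome Genome from [read_genome()].
#' @param min_reads,min_samples Support thresholds, see [support_filter()].
#' @return A data.frame with one row per distinct junction: coordinates,
#'   `junction_key`, `donor`, `acceptor`, `motif`, `n_supporting_samples`,
#'   and logicals `supported`, `canonical`, `pass`.
#' @export
passing_junctions <- function(support, genome, min_reads = 10,
                              min_samples = 3) {
  genome <- as_genome(genome)
  key <- junction_key(support$chrom, support$strand, support$start,
                      support$end)
  uj <- support[!duplicated(key), c("chrom", "start", "end", "strand")]
  uj$junction_key <- key[!duplicated(key)]
  nsupp <- tapply(support$unique_reads >= min_reads,
                  factor(key, levels = uj$junction_key), sum)
  uj$n_supporting_samples <- as.integer(nsupp[uj$junction_key])
  mot <- junction_motifs(uj, genome)
  uj$donor <- mot$donor
  uj$acceptor <- mot$acceptor
  uj$motif <- ifelse(is.na(uj$donor), "non_canonical",
                     classify_motif(ifelse(is.na(uj$donor), "NN", uj$donor),
                                    ifelse(is.na(uj$acceptor), "NN",
                                           uj$acceptor)))
  uj$supported <- uj$n_supporting_samples >= min_samples
  uj$canonical <- uj$motif == "canonical"
  uj$pass <- uj$supported & uj$canonical
  rownames(uj) <- NULL
  uj
}

# donor/acceptor dinucleotides for a junction table (strand-aware);
# strand "*" yields NA.
junction_motifs <- function(junctions, genome) {
  n <- nrow(junctions)
  donor <- acceptor <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    st <- junctions$strand[i]
    if (!st %in% c("+", "-")) next
    chrom <- junctions$chrom[i]
    s <- junctions$start[i]
    e <- junctions$end[i]
    if (st == "+") {
      donor[i] <- fetch_seq(genome, chrom, s, s + 1L, "+")
      acceptor[i] <- fetch_seq(genome, chrom, e - 1L, e, "+")
    } else {
      donor[i] <- fetch_seq(genome, chrom, e - 1L, e, "-")
      acceptor[i] <- fetch_seq(genome, chrom, s, s + 1L, "-")
    }
  }
  data.frame(donor = donor, acceptor = acceptor, stringsAsFactors = FALSE)
}

#' Build a splice-site position weight matrix
#'
#' Training sites are 13-mers: for donor sites 3 exonic + 10 intronic
#' nucleotides, for acceptor sites 10 intronic + 3 exonic, both read 5' to 3'
#' in transcript orientation. Position frequencies get a pseudocount and each
#' row is normalised to sum to 1.
#'
#' @param sites Character vector of 13-mers over A, C, G, T.
#' @param pseudocount Added to every (position, base) count; must be > 0 for
#'   strictly positive probabilities (default 0.5).
#' @param label Intron class label, e.g. `"U2"`, `"U12_GTAG"`, `"U12_ATAC"`.
#' @return A 13 x 4 probability matrix of class `"splice_pwm"`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, label = "U2") {
  if (!length(sites)) stop("need at least one training site")
  if (any(nchar(sites) != 13))
    stop("all training sites must be 13-mers")
  chars <- strsplit(toupper(sites), "", fixed = TRUE)
  bases <- c("A", "C", "G", "T")
  m <- matrix(match(unlist(chars), bases), ncol = 13, byrow = TRUE)
  if (anyNA(m)) stop("training sites must be over {A,C,G,T}")
  counts <- matrix(pseudocount, nrow = 13, ncol = 4,
                   dimnames = list(NULL, bases))
  for (p in 1:13) {
    tb <- tabulate(m[, p], nbins = 4)
    counts[p, ] <- counts[p, ] + tb
  }
  pwm <- counts / rowSums(counts)
  structure(pwm, class = "splice_pwm", label = label,
            pseudocount = pseudocount, n_sites = length(sites))
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat(sprintf("<splice_pwm> %s (13 positions, pseudocount %g)\n",
              attr(x, "label"), attr(x, "pseudocount")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Score a splice-site 13-mer against a PWM
#'
#' The raw score is the log2 likelihood ratio against a uniform background,
#' summed over positions; it is then min-max scaled to 0-100 so that the
#' per-position consensus sequence scores exactly 100 and the anti-consensus
#' exactly 0. Sequences containing `N` get `NA`.
#'
#' @param seqs Character vector of 13-mers.
#' @param pwm A `"splice_pwm"` from [build_pwm()].
#' @return Numeric vector of scores in `[0, 100]` (or `NA`).
#' @export
score_splice_site <- function(seqs, pwm) {
  lw <- log2(unclass(pwm) / 0.25)
  rmin <- sum(apply(lw, 1, min))
  rmax <- sum(apply(lw, 1, max))
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    s <- toupper(s)
    if (nchar(s) != 13) stop("splice-site sequences must be 13-mers")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(ch == "N")) return(NA_real_)
    idx <- match(ch, bases)
    if (anyNA(idx)) stop("invalid letter in splice-site sequence: ", s)
    raw <- sum(lw[cbind(1:13, idx)])
    100 * (raw - rmin) / (rmax - rmin)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default score thresholds for intron classification
#'
#' U12 introns require a 5' splice-site score above 75 and a 3' score above
#' 65 in the U12 matrices; U2 introns require both scores above 60 in the U2
#' matrices.
#'
#' @param u12_donor_min,u12_acceptor_min,u2_min Thresholds on the 0-100
#'   scale.
#' @return A list of thresholds.
#' @export
score_thresholds <- function(u12_donor_min = 75, u12_acceptor_min = 65,
                             u2_min = 60) {
  stopifnot(u12_donor_min >= 0, u12_donor_min <= 100,
            u12_acceptor_min >= 0, u12_acceptor_min <= 100,
            u2_min >= 0, u2_min <= 100)
  list(u12_donor_min = u12_donor_min, u12_acceptor_min = u12_acceptor_min,
       u2_min = u2_min)
}

#' Classify introns as U2, U12 or unclassified
#'
#' U12 takes precedence: an intron is U12 iff its U12 donor score exceeds the
#' donor threshold and its U12 acceptor score exceeds the acceptor threshold;
#' otherwise it is U2 iff both U2 scores exceed the U2 threshold; otherwise
#' unclassified. `NA` scores fail every comparison.
#'
#' @param u2_donor,u2_acceptor,u12_donor,u12_acceptor Numeric score vectors.
#' @param thresholds From [score_thresholds()].
#' @return Character vector over `{"U2", "U12", "unclassified"}`.
#' @export
classify_intron_type <- function(u2_donor, u2_acceptor, u12_donor,
                                 u12_acceptor,
                                 thresholds = score_thresholds()) {
  gt <- function(x, t) !is.na(x) & x > t
  is_u12 <- gt(u12_donor, thresholds$u12_donor_min) &
    gt(u12_acceptor, thresholds$u12_acceptor_min)
  is_u2 <- gt(u2_donor, thresholds$u2_min) & gt(u2_acceptor, thresholds$u2_min)
  ifelse(is_u12, "U12", ifelse(is_u2, "U2", "unclassified"))
}

#' Splice-site windows of every intron
#'
#' For each intron of each transcript, extracts the donor window (3 exonic +
#' 10 intronic nucleotides) and acceptor window (10 intronic + 3 exonic),
#' both 5' to 3' in transcript orientation.
#'
#' @param x A transcriptome.
#' @param genome Genome from [read_genome()].
#' @return [introns_df()] of `x` with extra columns `donor_seq`,
#'   `acceptor_seq`.
#' @export
splice_site_sequences <- function(x, genome) {
  genome <- as_genome(genome)
  idf <- introns_df(x)
  n <- nrow(idf)
  donor <- acceptor <- character(n)
  for (i in seq_len(n)) {
    chrom <- idf$chrom[i]
    s <- idf$start[i]
    e <- idf$end[i]
    if (idf$strand[i] == "+") {
      donor[i] <- fetch_seq(genome, chrom, s - 3L, s + 9L, "+")
      acceptor[i] <- fetch_seq(genome, chrom, e - 9L, e + 3L, "+")
    } else {
      donor[i] <- fetch_seq(genome, chrom, e - 9L, e + 3L, "-")
      acceptor[i] <- fetch_seq(genome, chrom, s - 3L, s + 9L, "-")
    }
  }
  idf$donor_seq <- donor
  idf$acceptor_seq <- acceptor
  idf
}

#' Score and classify all distinct introns of a transcriptome
#'
#' @param x A transcriptome.
#' @param genome Genome from [read_genome()].
#' @param models Splice-site models as returned by [default_splice_models()].
#' @param thresholds From [score_thresholds()].
#' @return One row per distinct intron with U2 and U12 donor/acceptor scores,
#'   the winning U12 variant, and the `intron_type` classification.
#' @export
score_introns <- function(x, genome, models = default_splice_models(),
                          thresholds = score_thresholds()) {
  ss <- splice_site_sequences(x, genome)
  ss <- ss[!duplicated(ss$junction_key),
           c("chrom", "start", "end", "strand", "junction_key",
             "donor_seq", "acceptor_seq")]
  ss$u2_donor <- score_splice_site(ss$donor_seq, models$U2$donor)
  ss$u2_acceptor <- score_splice_site(ss$acceptor_seq, models$U2$acceptor)
  d_gtag <- score_splice_site(ss$donor_seq, models$U12_GTAG$donor)
  a_gtag <- score_splice_site(ss$acceptor_seq, models$U12_GTAG$acceptor)
  d_atac <- score_splice_site(ss$donor_seq, models$U12_ATAC$donor)
  a_atac <- score_splice_site(ss$acceptor_seq, models$U12_ATAC$acceptor)
  use_atac <- !is.na(d_atac) & (is.na(d_gtag) | d_atac > d_gtag)
  ss$u12_variant <- ifelse(use_atac, "U12_ATAC", "U12_GTAG")
  ss$u12_donor <- ifelse(use_atac, d_atac, d_gtag)
  ss$u12_acceptor <- ifelse(use_atac, a_atac, a_gtag)
  ss$intron_type <- classify_intron_type(ss$u2_donor, ss$u2_acceptor,
                                         ss$u12_donor, ss$u12_acceptor,
                                         thresholds)
  rownames(ss) <- NULL
  ss
}

#' Default synthetic splice-site models
#'
#' Probability matrices for U2, U12 GT..AG and U12 AT..AC donor and acceptor
#' signals, derived from the consensus model used by the package's synthetic
#' data generator (they are synthetic stand-ins, not published plant
#' matrices; scores are comparable only within this implementation). The
#' terminal dinucleotides are near-fixed; other consensus positions carry
#' moderate weight.
#'
#' @return A list with elements `U2`, `U12_GTAG`, `U12_ATAC`, each a list of
#'   `donor` and `acceptor` `"splice_pwm"` matrices.
#' @export
default_splice_models <- function() {
  list(
    U2 = list(
      donor = consensus_pwm("CAGGTAAGTATTT", strong = 4:5, label = "U2"),
      acceptor = consensus_pwm("TTTTTTGCAGGTT", strong = 9:10, label = "U2")),
    U12_GTAG = list(
      donor = consensus_pwm("GAGGTATCCTTTT", strong = 4:5, p_cons = 0.8,
                            label = "U12_GTAG"),
      acceptor = consensus_pwm("TCCTTAACAGATC", strong = 9:10, p_cons = 0.8,
                               label = "U12_GTAG")),
    U12_ATAC = list(
      donor = consensus_pwm("GAGATATCCTTTT", strong = 4:5, p_cons = 0.8,
                            label = "U12_ATAC"),
      acceptor = consensus_pwm("TCCTTAAAACATC", strong = 9:10, p_cons = 0.8,
                               label = "U12_ATAC")))
}

# probability matrix straight from a consensus 13-mer: consensus base gets
# p_cons (p_strong at near-fixed positions), the rest is spread evenly.
consensus_pwm <- function(consensus, strong = integer(0), p_cons = 0.7,
                          p_strong = 0.94, label = "U2") {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  stopifnot(length(ch) == 13, all(ch %in% bases))
  pwm <- matrix(0, nrow = 13, ncol = 4, dimnames = list(NULL, bases))
  for (p in 1:13) {
    pc <- if (p %in% strong) p_strong else p_cons
    pwm[p, ] <- (1 - pc) / 3
    pwm[p, ch[p]] <- pc
  }
  structure(pwm, class = "splice_pwm", label = label, pseudocount = NA_real_,
            n_sites = NA_integer_)
}

#' Write / read a splice PWM as headered TSV
#'
#' Columns: `position`, `A`, `C`, `G`, `T`.
#'
#' @param pwm A `"splice_pwm"`.
#' @param path File path.
#' @return `write_pwm()` returns `path` invisibly; `read_pwm()` a
#'   `"splice_pwm"`.
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(position = 1:13, unclass(pwm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @param label Intron class label attached to the matrix read back.
#' @export
read_pwm <- function(path, label = "U2") {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!identical(names(df), c("position", "A", "C", "G", "T")))
    stop("unexpected PWM header in ", path)
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  rownames(m) <- NULL
  structure(m, class = "splice_pwm", label = label, pseudocount = NA_real_,
            n_sites = NA_integer_)
}
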