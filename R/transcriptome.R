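#' Build a transcriptome object
#'
#' A transcriptome is a named collection of strand-aware transcript models.
#' Each transcript is an ordered chain of exons on a single chromosome and
#' strand, and belongs to a gene. Exons are stored in genomic order as a
#' [GenomicRanges::GRanges] (1-based, closed intervals) with `transcript_id`
#' and `gene_id` metadata columns; within a transcript, consecutive exons must
#' be separated by at least one intronic base.
#'
#' @param exons A `GRanges` with metadata columns `transcript_id` and
#'   `gene_id`, or a data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `transcript_id`, `gene_id` (1-based closed coordinates).
#' @param name Label for the transcriptome (e.g. the assembly it came from).
#'
#' @return An object of class `"transcriptome"`.
#'
#' @examples
#' tx <- transcriptome(data.frame(
#'   chrom = "chr1", start = c(101, 301), end = c(200, 400), strand = "+",
#'   transcript_id = "t1", gene_id = "g1"))
#' introns(tx)
#'
#' @export
transcriptome <- function(exons, name = "transcriptome") {
  if (is.data.frame(exons)) {
    required <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
    miss <- setdiff(required, names(exons))
    if (length(miss))
      stop("exon data.frame is missing column(s): ", paste(miss, collapse = ", "))
    exons <- GenomicRanges::GRanges(
      seqnames = as.character(exons$chrom),
      ranges = IRanges::IRanges(exons$start, exons$end),
      strand = as.character(exons$strand),
      transcript_id = as.character(exons$transcript_id),
      gene_id = as.character(exons$gene_id))
  }
  if (!methods::is(exons, "GRanges"))
    stop("'exons' must be a GRanges or a data.frame")
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id))
    stop("exons need 'transcript_id' and 'gene_id' metadata columns")
  tid <- as.character(mc$transcript_id)
  gid <- as.character(mc$gene_id)
  if (length(exons)) {
    if (anyNA(tid) || any(!nzchar(tid)))
      stop("every exon needs a non-empty transcript_id")
    if (anyNA(gid) || any(!nzchar(gid)))
      stop("every exon needs a non-empty gene_id")
    if (any(!as.character(GenomicRanges::strand(exons)) %in% c("+", "-")))
      stop("exons must be stranded ('+' or '-')")
    if (any(GenomicRanges::width(exons) < 1))
      stop("exons must have width >= 1")
    ord <- order(tid, GenomicRanges::start(exons))
    exons <- exons[ord]
    tid <- tid[ord]
    chrom <- as.character(GenomicRanges::seqnames(exons))
    str <- as.character(GenomicRanges::strand(exons))
    gid <- as.character(S4Vectors::mcols(exons)$gene_id)
    one_per_tx <- function(v, what) {
      n <- tapply(v, tid, function(z) length(unique(z)))
      if (any(n > 1))
        stop("transcript(s) with more than one ", what, ": ",
             paste(utils::head(names(n)[n > 1], 3), collapse = ", "))
    }
    one_per_tx(chrom, "chromosome")
    one_per_tx(str, "strand")
    one_per_tx(gid, "gene_id")
    s <- GenomicRanges::start(exons)
    e <- GenomicRanges::end(exons)
    prev_e <- c(NA_integer_, e[-length(e)])
    bad <- which(duplicated(tid) & s <= prev_e + 1L)
    if (length(bad))
      stop("overlapping or adjacent exons in transcript(s): ",
           paste(unique(utils::head(tid[bad], 3)), collapse = ", "))
  }
  structure(list(name = name, exons = exons), class = "transcriptome")
}

empty_transcriptome <- function(name = "transcriptome") {
  transcriptome(GenomicRanges::GRanges(transcript_id = character(0),
                                       gene_id = character(0)),
                name = name)
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> %s: %d transcripts, %d genes, %d exons\n",
              x$name, n_transcripts(x), length(gene_ids(x)), length(x$exons)))
  invisible(x)
}

#' Transcript and gene identifiers
#'
#' @param x A transcriptome.
#' @return `transcript_ids()` and `gene_ids()` return character vectors of
#'   unique identifiers; `tx2gene()` a two-column data.frame mapping each
#'   transcript to its gene; `n_transcripts()` the transcript count.
#' @export
transcript_ids <- function(x) {
  unique(as.character(S4Vectors::mcols(x$exons)$transcript_id))
}

#' @rdname transcript_ids
#' @export
gene_ids <- function(x) {
  unique(as.character(S4Vectors::mcols(x$exons)$gene_id))
}

#' @rdname transcript_ids
#' @export
tx2gene <- function(x) {
  df <- unique(data.frame(
    transcript_id = as.character(S4Vectors::mcols(x$exons)$transcript_id),
    gene_id = as.character(S4Vectors::mcols(x$exons)$gene_id),
    stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' @rdname transcript_ids
#' @export
n_transcripts <- function(x) length(transcript_ids(x))

#' Split exons per transcript
#'
#' @param x A transcriptome.
#' @return A `GRangesList` of exons, one element per transcript, in
#'   transcript-id order; exons within each element are in genomic order.
#' @export
exons_by_transcript <- function(x) {
  tid <- as.character(S4Vectors::mcols(x$exons)$transcript_id)
  GenomicRanges::split(x$exons, factor(tid, levels = unique(tid)))
}

#' Subset a transcriptome to a set of transcripts
#'
#' @param x A transcriptome.
#' @param ids Transcript identifiers to keep.
#' @param name Optional new label.
#' @export
subset_transcripts <- function(x, ids, name = x$name) {
  tid <- as.character(S4Vectors::mcols(x$exons)$transcript_id)
  transcriptome(x$exons[tid %in% ids], name = name)
}

#' Genomic span of each transcript
#'
#' The span is the interval from the first exon's start to the last exon's
#' end, on the transcript's chromosome and strand.
#'
#' @param x A transcriptome.
#' @return A `GRanges` with one range per transcript and metadata columns
#'   `transcript_id` and `gene_id`.
#' @export
genomic_spans <- function(x) {
  if (!length(x$exons)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(transcript_id = character(0),
                                                 gene_id = character(0))
    return(gr)
  }
  grl <- exons_by_transcript(x)
  sp <- unlist(range(grl))
  t2g <- tx2gene(x)
  S4Vectors::mcols(sp)$transcript_id <- names(sp)
  S4Vectors::mcols(sp)$gene_id <-
    t2g$gene_id[match(names(sp), t2g$transcript_id)]
  names(sp) <- NULL
  sp
}

#' Introns of every transcript
#'
#' Intron i is the gap between exon i and exon i+1 in genomic order;
#' mono-exonic transcripts have no introns.
#'
#' @param x A transcriptome.
#' @return A `GRangesList` of introns, one element per transcript (possibly
#'   empty), same order as [exons_by_transcript()].
#' @export
introns <- function(x) {
  grl <- exons_by_transcript(x)
  if (!length(grl)) return(GenomicRanges::GRangesList())
  sp <- unlist(range(grl))
  GenomicRanges::psetdiff(sp, grl)
}

#' Flat intron table
#'
#' @param x A transcriptome.
#' @return A data.frame with one row per (transcript, intron):
#'   `transcript_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `junction_key`. Mono-exonic transcripts contribute no rows.
#' @export
introns_df <- function(x) {
  ic <- introns(x)
  empty <- data.frame(transcript_id = character(0), gene_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      junction_key = character(0), stringsAsFactors = FALSE)
  if (!length(ic)) return(empty)
  flat <- unlist(ic)
  if (!length(flat)) return(empty)
  tidn <- rep(names(ic), lengths(ic))
  t2g <- tx2gene(x)
  df <- data.frame(
    transcript_id = tidn,
    gene_id = t2g$gene_id[match(tidn, t2g$transcript_id)],
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat),
    end = GenomicRanges::end(flat),
    strand = as.character(GenomicRanges::strand(flat)),
    stringsAsFactors = FALSE)
  df$junction_key <- junction_key(df$chrom, df$strand, df$start, df$end)
  rownames(df) <- NULL
  df
}

#' Canonical key for a splice junction
#'
#' @param chrom,strand,start,end Junction coordinates (1-based first and last
#'   intronic base).
#' @return Character key `"chrom:strand:start-end"`.
#' @export
junction_key <- function(chrom, strand, start, end) {
  paste0(chrom, ":", strand, ":", start, "-", end)
}

#' Intron-chain identity keys
#'
#' Two transcripts receive the same key iff they lie on the same chromosome
#' and strand and have identical intron coordinates. The key is invariant
#' under changes to the outermost exon ends (UTR extent), which is what makes
#' it the identity used for redundancy removal. All mono-exonic transcripts
#' on the same chromosome and strand share the empty chain key.
#'
#' @param x A transcriptome.
#' @return Named character vector, one key per transcript.
#' @export
intron_chain_keys <- function(x) {
  ids <- transcript_ids(x)
  if (!length(ids)) return(stats::setNames(character(0), character(0)))
  sp <- genomic_spans(x)
  base <- stats::setNames(
    paste0(as.character(GenomicRanges::seqnames(sp)), ":",
           as.character(GenomicRanges::strand(sp)), ":"),
    S4Vectors::mcols(sp)$transcript_id)
  idf <- introns_df(x)
  if (nrow(idf)) {
    chains <- tapply(paste(idf$start, idf$end, sep = "-"),
                     factor(idf$transcript_id, levels = ids),
                     paste, collapse = "|")
    chains[is.na(chains)] <- ""
  } else {
    chains <- stats::setNames(rep("", length(ids)), ids)
  }
  stats::setNames(paste0(base[ids], chains[ids]), ids)
}

#' Gene spans
#'
#' @param x A transcriptome.
#' @return A data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start` (min exon start over the gene's transcripts), `end` (max exon
#'   end).
#' @export
gene_spans <- function(x) {
  if (!length(x$exons))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  gid <- as.character(S4Vectors::mcols(x$exons)$gene_id)
  chrom <- as.character(GenomicRanges::seqnames(x$exons))
  str <- as.character(GenomicRanges::strand(x$exons))
  s <- GenomicRanges::start(x$exons)
  e <- GenomicRanges::end(x$exons)
  genes <- unique(gid)
  df <- data.frame(
    gene_id = genes,
    chrom = chrom[match(genes, gid)],
    strand = str[match(genes, gid)],
    start = as.integer(tapply(s, factor(gid, levels = genes), min)),
    end = as.integer(tapply(e, factor(gid, levels = genes), max)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

gene_spans_granges <- function(x) {
  df <- gene_spans(x)
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(df$start, df$end),
                         strand = df$strand, gene_id = df$gene_id)
}
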