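#' Pad all transcripts of each gene to common end coordinates
#'
#' Every transcript's span is extended to the span of the transcript(s)
#' covering the longest region of the gene, by growing the first exon's
#' start and the last exon's end with cognate genomic sequence. No new exons
#' or junctions are created and intron chains are unchanged. The padded
#' transcriptome is the "QUASI" variant used for isoform quantification.
#'
#' @param x A transcriptome.
#' @param genome Genome from [read_genome()]; used to check chromosome
#'   bounds (padding beyond a chromosome end is an error).
#' @param name Label for the result.
#' @return The padded transcriptome; `attr(, "adjustments")` records per
#'   transcript the old/new span and the nucleotides added at the 5' and 3'
#'   ends in gene-strand orientation.
#' @export
pad_transcriptome <- function(x, genome, name = x$name) {
  genome <- as_genome(genome)
  lens <- chrom_lengths(genome)
  gsp <- gene_spans(x)
  bad <- gsp$start < 1 | gsp$end > lens[gsp$chrom]
  if (any(bad, na.rm = TRUE))
    stop("padded span exceeds chromosome bounds for gene(s): ",
         paste(utils::head(gsp$gene_id[bad], 3), collapse = ", "))
  ex <- x$exons
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  gid <- as.character(S4Vectors::mcols(ex)$gene_id)
  target_s <- gsp$start[match(gid, gsp$gene_id)]
  target_e <- gsp$end[match(gid, gsp$gene_id)]
  sp <- genomic_spans(x)
  spid <- S4Vectors::mcols(sp)$transcript_id
  old_s <- stats::setNames(GenomicRanges::start(sp), spid)
  old_e <- stats::setNames(GenomicRanges::end(sp), spid)
  first <- !duplicated(tid)
  last <- !duplicated(tid, fromLast = TRUE)
  GenomicRanges::start(ex)[first] <- target_s[first]
  GenomicRanges::end(ex)[last] <- target_e[last]
  out <- transcriptome(ex, name = name)
  t2g <- tx2gene(x)
  ids <- t2g$transcript_id
  strand <- stats::setNames(as.character(GenomicRanges::strand(sp)), spid)
  new_s <- gsp$start[match(t2g$gene_id, gsp$gene_id)]
  new_e <- gsp$end[match(t2g$gene_id, gsp$gene_id)]
  left <- old_s[ids] - new_s
  right <- new_e - old_e[ids]
  adj <- data.frame(
    transcript_id = ids, gene_id = t2g$gene_id, mode = "pad",
    old_start = unname(old_s[ids]), old_end = unname(old_e[ids]),
    new_start = new_s, new_end = new_e,
    added_5p = ifelse(strand[ids] == "+", left, right),
    added_3p = ifelse(strand[ids] == "+", right, left),
    stringsAsFactors = FALSE)
  rownames(adj) <- NULL
  attr(out, "adjustments") <- adj
  out
}

#' @rdname pad_transcriptome
#' @export
build_quasi <- function(x, genome, name = paste0(x$name, "-QUASI")) {
  pad_transcriptome(x, genome, name = name)
}

#' Trim all transcripts of each gene to common end coordinates
#'
#' Every transcript is clipped to the window covered by the transcript(s)
#' spanning the shortest region of the gene (maximum span start to minimum
#' span end). Exons outside the window are dropped; when a window edge falls
#' inside an intron, the transcript is truncated at the last complete exon
#' boundary inside the window, so no partial introns are created. Genes
#' whose window is empty are left unchanged with a warning; transcripts left
#' without exons are removed with a warning.
#'
#' @param x A transcriptome.
#' @param name Label for the result.
#' @return The trimmed transcriptome; `attr(, "adjustments")` records per
#'   transcript the old and new spans, `attr(, "removed")` lists transcripts
#'   dropped entirely.
#' @export
trim_transcriptome <- function(x, name = x$name) {
  sp <- genomic_spans(x)
  spid <- S4Vectors::mcols(sp)$transcript_id
  spg <- S4Vectors::mcols(sp)$gene_id
  ws <- tapply(GenomicRanges::start(sp), spg, max)
  we <- tapply(GenomicRanges::end(sp), spg, min)
  skipped <- names(ws)[ws > we]
  if (length(skipped))
    warning("empty trim window; gene(s) left unchanged: ",
            paste(utils::head(skipped, 3), collapse = ", "))
  ex <- x$exons
  gid <- as.character(S4Vectors::mcols(ex)$gene_id)
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  trim_gene <- !gid %in% skipped
  new_s <- ifelse(trim_gene, pmax(GenomicRanges::start(ex), ws[gid]),
                  GenomicRanges::start(ex))
  new_e <- ifelse(trim_gene, pmin(GenomicRanges::end(ex), we[gid]),
                  GenomicRanges::end(ex))
  keep <- new_s <= new_e
  removed_tx <- setdiff(unique(tid), unique(tid[keep]))
  if (length(removed_tx))
    warning("transcript(s) removed by trimming (no exon inside window): ",
            paste(utils::head(removed_tx, 3), collapse = ", "))
  ex <- ex[keep]
  GenomicRanges::ranges(ex) <- IRanges::IRanges(new_s[keep], new_e[keep])
  out <- transcriptome(ex, name = name)
  osp <- stats::setNames(GenomicRanges::start(sp), spid)
  oep <- stats::setNames(GenomicRanges::end(sp), spid)
  nsp2 <- genomic_spans(out)
  nid <- S4Vectors::mcols(nsp2)$transcript_id
  adj <- data.frame(
    transcript_id = nid,
    gene_id = S4Vectors::mcols(nsp2)$gene_id,
    mode = "trim",
    old_start = unname(osp[nid]), old_end = unname(oep[nid]),
    new_start = GenomicRanges::start(nsp2),
    new_end = GenomicRanges::end(nsp2),
    stringsAsFactors = FALSE)
  rownames(adj) <- NULL
  attr(out, "adjustments") <- adj
  attr(out, "removed") <- removed_tx
  out
}

#' Extract transcript (mRNA) sequences
#'
#' Each sequence is the concatenation of the transcript's exon sequences in
#' 5' to 3' transcript orientation (reverse-complemented for minus-strand
#' transcripts).
#'
#' @param x A transcriptome.
#' @param genome Genome from [read_genome()].
#' @return A [Biostrings::DNAStringSet] named by transcript id.
#' @export
extract_sequences <- function(x, genome) {
  genome <- as_genome(genome)
  grl <- exons_by_transcript(x)
  out <- vapply(seq_along(grl), function(i) {
    gr <- grl[[i]]
    chrom <- as.character(GenomicRanges::seqnames(gr))[1]
    parts <- vapply(seq_along(gr), function(j) {
      fetch_seq(genome, chrom, GenomicRanges::start(gr)[j],
                GenomicRanges::end(gr)[j], "+")
    }, character(1))
    s <- paste(parts, collapse = "")
    if (as.character(GenomicRanges::strand(gr))[1] == "-")
      s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(out, names(grl)))
}

#' Write sequences as FASTA
#'
#' @param seqs A named `DNAStringSet` or `AAStringSet` (or named character
#'   vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
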