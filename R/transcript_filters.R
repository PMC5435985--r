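#' Filter reports
#'
#' Every transcript-level filter returns a `filter_report` partitioning the
#' input transcripts into `kept` and `removed` (with a reason per removed
#' transcript), plus any gene reassignments. Apply a report with
#' [apply_filter()].
#'
#' @name filter_report
NULL

new_filter_report <- function(filter, kept, removed_ids, reasons,
                              reassigned = character(0)) {
  removed <- data.frame(transcript_id = removed_ids, reason = reasons,
                        stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  structure(list(filter = filter, kept = kept, removed = removed,
                 reassigned = reassigned),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d kept, %d removed",
              x$filter, length(x$kept), nrow(x$removed)))
  if (length(x$reassigned))
    cat(sprintf(", %d reassigned", length(x$reassigned)))
  cat("\n")
  if (nrow(x$removed)) {
    tb <- table(x$removed$reason)
    for (r in names(tb)) cat(sprintf("  %s: %d\n", r, tb[[r]]))
  }
  invisible(x)
}

#' Apply a filter report to a transcriptome
#'
#' @param x The transcriptome the report was computed on.
#' @param report A `filter_report`.
#' @return The filtered transcriptome (gene reassignments applied).
#' @export
apply_filter <- function(x, report) {
  ex <- x$exons
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  ex <- ex[tid %in% report$kept]
  if (length(report$reassigned)) {
    tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
    hit <- tid %in% names(report$reassigned)
    S4Vectors::mcols(ex)$gene_id[hit] <-
      unname(report$reassigned[tid[hit]])
  }
  transcriptome(ex, name = x$name)
}

#' Remove transcripts with unsupported or non-canonical junctions
#'
#' A multi-exon transcript is kept iff every one of its introns is in the
#' passing junction set; mono-exonic transcripts pass vacuously. When the
#' full junction table is supplied, removal reasons distinguish
#' `non_canonical_junction` (a failing intron whose motif is non-canonical)
#' from `unsupported_junction`.
#'
#' @param x A transcriptome.
#' @param junctions Either the junction table from [passing_junctions()] or a
#'   character vector of passing junction keys (see [junction_key()]).
#' @return A [filter_report].
#' @export
filter_by_junctions <- function(x, junctions) {
  if (is.data.frame(junctions)) {
    pass_keys <- junctions$junction_key[junctions$pass]
    noncanon_keys <- junctions$junction_key[!junctions$canonical]
  } else {
    pass_keys <- as.character(junctions)
    noncanon_keys <- character(0)
  }
  ids <- transcript_ids(x)
  idf <- introns_df(x)
  bad <- idf[!idf$junction_key %in% pass_keys, , drop = FALSE]
  removed_ids <- unique(bad$transcript_id)
  reasons <- vapply(removed_ids, function(id) {
    k <- bad$junction_key[bad$transcript_id == id]
    if (any(k %in% noncanon_keys)) "non_canonical_junction"
    else "unsupported_junction"
  }, character(1), USE.NAMES = FALSE)
  new_filter_report("junctions", setdiff(ids, removed_ids), removed_ids,
                    reasons)
}

#' Remove antisense transcripts contained in annotated genes
#'
#' A transcript is removed iff its genomic span is completely contained in
#' the span of a reference gene on the same chromosome but the opposite
#' strand. Reference gene spans run from the minimum exon start to the
#' maximum exon end over all of the gene's transcripts.
#'
#' @param x A transcriptome.
#' @param reference Reference annotation as a [transcriptome].
#' @return A [filter_report].
#' @export
filter_antisense <- function(x, reference) {
  ids <- transcript_ids(x)
  sp <- genomic_spans(x)
  ref <- gene_spans_granges(reference)
  removed_ids <- character(0)
  if (length(sp) && length(ref)) {
    hits <- GenomicRanges::findOverlaps(sp, ref, type = "within",
                                        ignore.strand = TRUE)
    opp <- as.character(GenomicRanges::strand(sp))[S4Vectors::queryHits(hits)] !=
      as.character(GenomicRanges::strand(ref))[S4Vectors::subjectHits(hits)]
    removed_ids <- unique(
      S4Vectors::mcols(sp)$transcript_id[S4Vectors::queryHits(hits)[opp]])
  }
  new_filter_report("antisense", setdiff(ids, removed_ids), removed_ids,
                    rep("antisense_contained", length(removed_ids)))
}

#' Remove transcripts from unknown genes
#'
#' Transcripts whose gene_id is in the known set are kept. A transcript with
#' a novel gene_id is rescued - reassigned to a known gene and kept - if it
#' has at least 1 bp of same-strand exon overlap with that gene's exons
#' (ties broken by total overlap); otherwise it is removed.
#'
#' @param x A transcriptome.
#' @param reference Reference annotation as a [transcriptome]; its exons
#'   define overlap-based rescue.
#' @param known_gene_ids Gene ids considered known (default: the reference's
#'   gene ids).
#' @return A [filter_report]; rescued transcripts appear in `$reassigned`.
#' @export
filter_unknown_genes <- function(x, reference,
                                 known_gene_ids = gene_ids(reference)) {
  t2g <- tx2gene(x)
  known <- t2g$gene_id %in% known_gene_ids
  candidates <- t2g$transcript_id[!known]
  reassigned <- character(0)
  removed_ids <- character(0)
  if (length(candidates)) {
    tid <- as.character(S4Vectors::mcols(x$exons)$transcript_id)
    cand_ex <- x$exons[tid %in% candidates]
    hits <- GenomicRanges::findOverlaps(cand_ex, reference$exons,
                                        ignore.strand = FALSE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ow <- GenomicRanges::width(GenomicRanges::pintersect(cand_ex[q],
                                                           reference$exons[s]))
      ctid <- as.character(S4Vectors::mcols(cand_ex)$transcript_id)[q]
      rgid <- as.character(S4Vectors::mcols(reference$exons)$gene_id)[s]
      agg <- stats::aggregate(ow, list(transcript_id = ctid, gene_id = rgid),
                              sum)
      agg <- agg[order(agg$transcript_id, -agg$x, agg$gene_id), ]
      agg <- agg[!duplicated(agg$transcript_id), ]
      reassigned <- stats::setNames(agg$gene_id, agg$transcript_id)
    }
    removed_ids <- setdiff(candidates, names(reassigned))
  }
  new_filter_report("unknown_genes",
                    setdiff(t2g$transcript_id, removed_ids), removed_ids,
                    rep("unknown_gene", length(removed_ids)),
                    reassigned = reassigned)
}

#' Remove transcripts with no or very low expression
#'
#' A transcript is kept iff its TPM exceeds `min_tpm` (strictly) in at least
#' `min_samples` distinct samples. Transcripts absent from the
#' quantification matrix are treated as all-zero and removed, with a
#' warning.
#'
#' @param x A transcriptome.
#' @param tpm TPM matrix from [read_quant()] (transcripts x samples).
#' @param min_tpm Strict TPM threshold (default 1).
#' @param min_samples Minimum number of qualifying samples (default 3).
#' @return A [filter_report].
#' @export
filter_low_expression <- function(x, tpm, min_tpm = 1, min_samples = 3) {
  ids <- transcript_ids(x)
  missing <- setdiff(ids, rownames(tpm))
  if (length(missing))
    warning(length(missing), " transcript(s) absent from the ",
            "quantification table; treated as unexpressed")
  present <- intersect(ids, rownames(tpm))
  nq <- rowSums(tpm[present, , drop = FALSE] > min_tpm)
  kept <- present[nq >= min_samples]
  removed_ids <- setdiff(ids, kept)
  new_filter_report("low_expression", kept, removed_ids,
                    rep("low_expression", length(removed_ids)))
}
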