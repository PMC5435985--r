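#' Remove redundant transcripts
#'
#' Within each gene, at most one multi-exon transcript per intron chain is
#' retained: the representative is the transcript with the longest genomic
#' span (keeping maximal UTR extent), with ties broken by `priority` (lower
#' wins; used by [merge_step()] to prefer the base transcriptome) and then by
#' lexicographically smallest transcript id. Mono-exonic transcripts are
#' redundant only when their spans are identical within the same gene.
#'
#' @param x A transcriptome.
#' @param priority Optional named numeric vector (transcript id -> priority,
#'   lower preferred). Unnamed transcripts get priority 0.
#' @return The de-duplicated transcriptome. The dropped transcripts are
#'   recorded in `attr(, "removed_redundant")` as a data.frame with columns
#'   `transcript_id` and `kept_as`.
#' @export
remove_redundant <- function(x, priority = NULL) {
  ids <- transcript_ids(x)
  if (!length(ids)) {
    out <- x
    attr(out, "removed_redundant") <-
      data.frame(transcript_id = character(0), kept_as = character(0),
                 stringsAsFactors = FALSE)
    return(out)
  }
  t2g <- tx2gene(x)
  sp <- genomic_spans(x)
  spid <- S4Vectors::mcols(sp)$transcript_id
  keys <- intron_chain_keys(x)
  nex <- lengths(exons_by_transcript(x))
  width <- stats::setNames(GenomicRanges::width(sp), spid)
  start <- stats::setNames(GenomicRanges::start(sp), spid)
  end <- stats::setNames(GenomicRanges::end(sp), spid)
  gene <- stats::setNames(t2g$gene_id, t2g$transcript_id)
  prio <- rep(0, length(ids))
  names(prio) <- ids
  if (!is.null(priority)) {
    hit <- intersect(ids, names(priority))
    prio[hit] <- priority[hit]
  }
  group <- ifelse(nex[ids] > 1,
                  paste0(gene[ids], "\r", keys[ids]),
                  paste0(gene[ids], "\rmono\r", keys[ids], start[ids], "-",
                         end[ids]))
  ord <- order(group, -width[ids], prio[ids], ids)
  oids <- ids[ord]
  ogroup <- group[ord]
  rep_of <- stats::setNames(oids[!duplicated(ogroup)][match(ogroup,
                                                            unique(ogroup))],
                            oids)
  dropped <- oids[oids != rep_of[oids]]
  out <- subset_transcripts(x, setdiff(ids, dropped))
  attr(out, "removed_redundant") <- data.frame(
    transcript_id = dropped,
    kept_as = unname(rep_of[dropped]),
    stringsAsFactors = FALSE)
  out
}

#' Merge an incoming transcriptome into a base transcriptome
#'
#' Gene ids of incoming transcripts are reconciled to the base by
#' same-strand exon overlap (an incoming transcript overlapping exactly one
#' base gene adopts that gene's id; one overlapping two or more base genes is
#' kept unchanged and flagged). The union of transcripts is then
#' de-duplicated with [remove_redundant()], preferring the base
#' representative unless the incoming transcript has a longer genomic span.
#'
#' @param base,incoming Transcriptomes. Incoming transcript ids colliding
#'   with base ids are suffixed with `".in"`.
#' @param name Label for the merged transcriptome.
#' @return The merged transcriptome; `attr(, "merge_report")` holds counts
#'   and the flagged transcripts, `attr(, "removed_redundant")` the dropped
#'   duplicates.
#' @export
merge_step <- function(base, incoming, name = base$name) {
  in_ex <- incoming$exons
  in_tid <- as.character(S4Vectors::mcols(in_ex)$transcript_id)
  flagged <- character(0)
  if (length(in_ex) && length(base$exons)) {
    hits <- GenomicRanges::findOverlaps(in_ex, base$exons,
                                        ignore.strand = FALSE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ow <- GenomicRanges::width(GenomicRanges::pintersect(in_ex[q],
                                                           base$exons[s]))
      bgid <- as.character(S4Vectors::mcols(base$exons)$gene_id)[s]
      agg <- stats::aggregate(ow, list(transcript_id = in_tid[q],
                                       gene_id = bgid), sum)
      ngene <- table(agg$transcript_id)
      flagged <- names(ngene)[ngene > 1]
      agg <- agg[!agg$transcript_id %in% flagged, ]
      if (nrow(agg)) {
        map <- stats::setNames(agg$gene_id, agg$transcript_id)
        hit <- in_tid %in% names(map)
        S4Vectors::mcols(in_ex)$gene_id[hit] <- unname(map[in_tid[hit]])
      }
    }
  }
  collide <- in_tid %in% transcript_ids(base)
  if (any(collide)) {
    new_id <- paste0(in_tid, ".in")
    S4Vectors::mcols(in_ex)$transcript_id[collide] <- new_id[collide]
    in_tid[collide] <- new_id[collide]
  }
  combined <- transcriptome(c(base$exons, in_ex), name = name)
  prio <- stats::setNames(
    c(rep(0, length(transcript_ids(base))), rep(1, length(unique(in_tid)))),
    c(transcript_ids(base), unique(in_tid)))
  out <- remove_redundant(combined, priority = prio)
  dropped <- attr(out, "removed_redundant")
  attr(out, "merge_report") <- list(
    n_base = n_transcripts(base),
    n_incoming = n_transcripts(incoming),
    n_added = n_transcripts(out) - n_transcripts(base) +
      sum(dropped$transcript_id %in% transcript_ids(base)),
    n_dropped = nrow(dropped),
    flagged = flagged)
  out
}

#' Run a step-wise merge plan
#'
#' Left fold of [merge_step()] over an ordered list of transcriptomes: the
#' first input is de-duplicated, then each subsequent transcriptome is merged
#' in, with redundancy removal after every step.
#'
#' @param txs A list of transcriptomes, in merge order.
#' @param labels Step labels (default: the transcriptome names).
#' @param name Label for the final transcriptome.
#' @return A list with `transcriptome` (the merged result) and `report`
#'   (a data.frame of per-step counts: label, incoming, dropped, total).
#' @export
run_merge_plan <- function(txs, labels = NULL,
                           name = "merged") {
  stopifnot(length(txs) >= 1)
  if (is.null(labels))
    labels <- vapply(txs, function(t) t$name, character(1))
  if (anyDuplicated(labels)) stop("merge plan labels must be unique")
  cur <- remove_redundant(txs[[1]])
  rep0 <- attr(cur, "removed_redundant")
  report <- data.frame(step = 1L, label = labels[1],
                       n_incoming = n_transcripts(txs[[1]]),
                       n_dropped = nrow(rep0),
                       n_total = n_transcripts(cur),
                       stringsAsFactors = FALSE)
  dropped_all <- rep0
  for (i in seq_along(txs)[-1]) {
    cur <- merge_step(cur, txs[[i]], name = name)
    mr <- attr(cur, "merge_report")
    dr <- attr(cur, "removed_redundant")
    dropped_all <- rbind(dropped_all, dr)
    report <- rbind(report, data.frame(
      step = i, label = labels[i], n_incoming = mr$n_incoming,
      n_dropped = mr$n_dropped, n_total = n_transcripts(cur),
      stringsAsFactors = FALSE))
  }
  cur$name <- name
  list(transcriptome = cur, report = report, removed = dropped_all)
}
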