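#' Pairwise alternative-splicing event detection
#'
#' Compares the intron chains of two isoforms of the same gene inside their
#' overlapping genomic window and classifies each local structural
#' difference:
#' * `IR` - an intron of one isoform lies fully inside an exon of the other
#'   (the retaining isoform is the AS form);
#' * `Alt5` / `Alt3` - two overlapping introns share their acceptor but
#'   differ at the donor (`Alt5`), or share the donor and differ at the
#'   acceptor (`Alt3`), strand-aware; the isoform with the shorter intron
#'   (more exonic sequence included) is the AS form;
#' * `ES` - an intron of one isoform shares its donor with one intron and
#'   its acceptor with a later intron of the other, skipping at least one
#'   exon in between (the skipping isoform is the AS form);
#' * anything else is `unclassified` and carries no AS/FS designation.
#'
#' @param x A transcriptome.
#' @param tx_a,tx_b Transcript ids of the same gene.
#' @return A data.frame with columns `type`, `chrom`, `strand`, `start`,
#'   `end` (the event-local interval: the retained intron, the alternative
#'   region, or the skipped exon(s)), `as_id`, `fs_id`. Zero rows for
#'   identical structures.
#' @export
detect_events_pairwise <- function(x, tx_a, tx_b) {
  t2g <- tx2gene(x)
  ga <- t2g$gene_id[t2g$transcript_id == tx_a]
  gb <- t2g$gene_id[t2g$transcript_id == tx_b]
  if (!length(ga) || !length(gb)) stop("unknown transcript id")
  if (ga != gb) stop("transcripts belong to different genes: ", ga, " vs ",
                     gb)
  grl <- exons_by_transcript(x)
  exa <- grl[[tx_a]]
  exb <- grl[[tx_b]]
  strand <- as.character(GenomicRanges::strand(exa))[1]
  chrom <- as.character(GenomicRanges::seqnames(exa))[1]
  intr <- function(gr) {
    if (length(gr) < 2) return(data.frame(start = integer(0),
                                          end = integer(0)))
    data.frame(start = GenomicRanges::end(gr)[-length(gr)] + 1L,
               end = GenomicRanges::start(gr)[-1] - 1L)
  }
  ia <- intr(exa)
  ib <- intr(exb)
  exdf <- function(gr) data.frame(start = GenomicRanges::start(gr),
                                  end = GenomicRanges::end(gr))
  ev <- pairwise_event_core(ia, ib, exdf(exa), exdf(exb), strand,
                            tx_a, tx_b)
  if (nrow(ev)) {
    ev$chrom <- chrom
    ev$strand <- strand
    ev <- ev[, c("type", "chrom", "strand", "start", "end", "as_id",
                 "fs_id")]
  } else {
    ev <- data.frame(type = character(0), chrom = character(0),
                     strand = character(0), start = integer(0),
                     end = integer(0), as_id = character(0),
                     fs_id = character(0), stringsAsFactors = FALSE)
  }
  ev
}

# core classifier on plain intron/exon coordinate tables
pairwise_event_core <- function(ia, ib, exa, exb, strand, id_a, id_b) {
  span_a <- c(min(exa$start), max(exa$end))
  span_b <- c(min(exb$start), max(exb$end))
  win <- c(max(span_a[1], span_b[1]), min(span_a[2], span_b[2]))
  keya <- paste(ia$start, ia$end)
  keyb <- paste(ib$start, ib$end)
  in_win <- function(df) df$start >= win[1] & df$end <= win[2]
  ua <- ia[!keya %in% keyb & in_win(ia), , drop = FALSE]
  ub <- ib[!keyb %in% keya & in_win(ib), , drop = FALSE]
  used_a <- rep(FALSE, nrow(ua))
  used_b <- rep(FALSE, nrow(ub))
  events <- list()
  add <- function(type, s, e, as_id, fs_id) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, start = as.integer(s), end = as.integer(e),
      as_id = as_id, fs_id = fs_id, stringsAsFactors = FALSE)
  }
  # intron retention: unique intron spliced by one, exonic in the other
  check_ir <- function(u, used, other_ex, spliced_id, retained_id) {
    for (i in seq_len(nrow(u))) {
      if (used[i]) next
      if (any(other_ex$start <= u$start[i] & other_ex$end >= u$end[i])) {
        add("IR", u$start[i], u$end[i], retained_id, spliced_id)
        used[i] <- TRUE
      }
    }
    used
  }
  used_a <- check_ir(ua, used_a, exb, id_a, id_b)
  used_b <- check_ir(ub, used_b, exa, id_b, id_a)
  # exon skipping: one long intron spanning two introns + >=1 exon of the
  # other isoform
  check_es <- function(u, used, other_i, other_ex, skip_id, incl_id,
                       mark_other) {
    for (i in seq_len(nrow(u))) {
      if (used[i]) next
      p <- which(other_i$start == u$start[i])
      q <- which(other_i$end == u$end[i])
      if (!length(p) || !length(q) || q[1] <= p[1]) next
      inside <- other_ex$start > u$start[i] & other_ex$end < u$end[i]
      if (!any(inside)) next
      add("ES", min(other_ex$start[inside]), max(other_ex$end[inside]),
          skip_id, incl_id)
      used[i] <- TRUE
      mark_other(u$start[i], u$end[i])
    }
    used
  }
  used_a <- check_es(ua, used_a, ib, exb, id_a, id_b, function(s, e) {
    used_b[ub$start == s | ub$end == e] <<- TRUE
  })
  used_b <- check_es(ub, used_b, ia, exa, id_b, id_a, function(s, e) {
    used_a[ua$start == s | ua$end == e] <<- TRUE
  })
  # alternative donor / acceptor: overlapping introns sharing one boundary
  for (i in seq_len(nrow(ua))) {
    if (used_a[i]) next
    for (j in seq_len(nrow(ub))) {
      if (used_b[j]) next
      s1 <- ua$start[i]; e1 <- ua$end[i]
      s2 <- ub$start[j]; e2 <- ub$end[j]
      if (e1 < s2 || e2 < s1) next  # no overlap
      same_start <- s1 == s2
      same_end <- e1 == e2
      if (same_start == same_end) next  # both differ -> unclassified later
      if (same_end) {
        # start boundary differs: donor side on '+', acceptor side on '-'
        type <- if (strand == "+") "Alt5" else "Alt3"
        s <- min(s1, s2); e <- max(s1, s2) - 1L
      } else {
        type <- if (strand == "+") "Alt3" else "Alt5"
        s <- min(e1, e2) + 1L; e <- max(e1, e2)
      }
      # AS form = shorter intron (keeps more exonic sequence)
      if ((e1 - s1) < (e2 - s2)) add(type, s, e, id_a, id_b)
      else add(type, s, e, id_b, id_a)
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      break
    }
  }
  for (i in which(!used_a))
    add("unclassified", ua$start[i], ua$end[i], NA_character_,
        NA_character_)
  for (j in which(!used_b))
    add("unclassified", ub$start[j], ub$end[j], NA_character_,
        NA_character_)
  if (!length(events))
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0), as_id = character(0),
                      fs_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Event identifier
#'
#' @param gene_id,type,chrom,start,end Event fields.
#' @return `"gene:type:chrom:start-end"`.
#' @export
as_event_id <- function(gene_id, type, chrom, start, end) {
  paste0(gene_id, ":", type, ":", chrom, ":", start, "-", end)
}

#' Detect and aggregate AS events across a transcriptome
#'
#' Runs [detect_events_pairwise()] on every pair of isoforms of each gene
#' and aggregates pairwise calls with identical (type, interval) into one
#' event: the AS transcript set is the union of AS calls, the FS set the
#' union of FS calls minus the AS set. Unclassified differences are dropped.
#'
#' @param x A transcriptome.
#' @return A data.frame with one row per event: `event_id`, `gene_id`,
#'   `type`, `chrom`, `strand`, `start`, `end`, `as_ids`, `fs_ids`
#'   (comma-separated transcript ids).
#' @export
detect_events <- function(x) {
  t2g <- tx2gene(x)
  out <- list()
  for (g in unique(t2g$gene_id)) {
    txs <- sort(t2g$transcript_id[t2g$gene_id == g])
    if (length(txs) < 2) next
    pw <- list()
    for (i in seq_along(txs)[-length(txs)])
      for (j in seq.int(i + 1L, length(txs)))
        pw[[length(pw) + 1L]] <- detect_events_pairwise(x, txs[i], txs[j])
    pw <- do.call(rbind, pw)
    pw <- pw[pw$type != "unclassified", , drop = FALSE]
    if (!nrow(pw)) next
    key <- paste(pw$type, pw$start, pw$end)
    for (k in unique(key)) {
      rows <- pw[key == k, ]
      as_set <- sort(unique(rows$as_id))
      fs_set <- sort(setdiff(unique(rows$fs_id), as_set))
      out[[length(out) + 1L]] <- data.frame(
        event_id = as_event_id(g, rows$type[1], rows$chrom[1],
                               rows$start[1], rows$end[1]),
        gene_id = g, type = rows$type[1], chrom = rows$chrom[1],
        strand = rows$strand[1], start = rows$start[1], end = rows$end[1],
        as_ids = paste(as_set, collapse = ","),
        fs_ids = paste(fs_set, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), as_ids = character(0),
                      fs_ids = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$gene_id, df$start, df$type), ]
  rownames(df) <- NULL
  df
}

#' AS/FS splicing ratios from TPMs
#'
#' For each event and sample, the ratio of the summed TPMs of the AS
#' transcript set to the summed TPMs of the FS set. A zero FS total gives an
#' undefined (NA) ratio, flagged and excluded from correlations. Ratios are
#' invariant to rescaling all TPMs of a sample.
#'
#' @param events Event table from [detect_events()] (or with the same
#'   `event_id`, `as_ids`, `fs_ids` columns).
#' @param tpm TPM matrix from [read_quant()].
#' @param source Label recorded in the output (default `"rnaseq"`).
#' @return A data.frame with `event_id`, `sample_id`, `ratio`, `undefined`,
#'   `source`.
#' @export
splicing_ratios <- function(events, tpm, source = "rnaseq") {
  samples <- colnames(tpm)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    as_set <- strsplit(events$as_ids[i], ",", fixed = TRUE)[[1]]
    fs_set <- strsplit(events$fs_ids[i], ",", fixed = TRUE)[[1]]
    missing <- setdiff(c(as_set, fs_set), rownames(tpm))
    if (length(missing))
      stop("event ", events$event_id[i], ": transcript(s) absent from the ",
           "quantification table: ", paste(missing, collapse = ", "))
    as_sum <- colSums(tpm[as_set, , drop = FALSE])
    fs_sum <- colSums(tpm[fs_set, , drop = FALSE])
    ratio <- ifelse(fs_sum > 0, as_sum / fs_sum, NA_real_)
    out[[i]] <- data.frame(event_id = events$event_id[i],
                           sample_id = samples, ratio = unname(ratio),
                           undefined = unname(fs_sum == 0), source = source,
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' AS/FS splicing ratios from peak areas
#'
#' Experimental splicing ratios: for each event and sample, each AS
#' product's peak area is divided by the area of the (single) fully spliced
#' product.
#'
#' @param peaks A data.frame with columns `gene_id`, `event_id`,
#'   `product_label` (`"FS"` for the fully spliced product, anything else
#'   for AS products), `sample_id`, `peak_area`.
#' @return A data.frame with `event_id`, `product_label`, `sample_id`,
#'   `ratio`, `source = "hr_rtpcr"`; one row per AS product.
#' @export
splicing_ratios_from_peaks <- function(peaks) {
  need <- c("gene_id", "event_id", "product_label", "sample_id", "peak_area")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak-area table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(peaks$peak_area < 0)) stop("peak areas must be >= 0")
  is_fs <- peaks$product_label == "FS"
  key <- paste(peaks$event_id, peaks$sample_id, sep = "\r")
  fs_n <- table(key[is_fs])
  all_keys <- unique(key)
  bad <- setdiff(all_keys, names(fs_n)[fs_n == 1])
  if (length(bad)) {
    es <- strsplit(bad[1], "\r", fixed = TRUE)[[1]]
    stop("event ", es[1], ", sample ", es[2],
         ": expected exactly one FS row")
  }
  fs_area <- stats::setNames(peaks$peak_area[is_fs], key[is_fs])
  as_rows <- peaks[!is_fs, , drop = FALSE]
  df <- data.frame(event_id = as_rows$event_id,
                   product_label = as_rows$product_label,
                   sample_id = as_rows$sample_id,
                   ratio = as_rows$peak_area /
                     unname(fs_area[key[!is_fs]]),
                   source = "hr_rtpcr", stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Concordance between two sets of splicing ratios
#'
#' Records are paired on (event_id, sample_id); when one side carries
#' multiple AS products per event (HR RT-PCR), their ratios are summed per
#' pair first. Undefined (NA) ratios are excluded pairwise. Pearson's
#' product-moment correlation and Spearman's rank correlation (average ranks
#' for ties) are computed over the pooled vector pair.
#'
#' @param x,y Ratio tables with columns `event_id`, `sample_id`, `ratio`
#'   (e.g. from [splicing_ratios()] and [splicing_ratios_from_peaks()]).
#' @return A list with `pearson`, `spearman` and `n` (pairs used).
#' @export
concordance <- function(x, y) {
  agg <- function(df) stats::aggregate(
    ratio ~ event_id + sample_id, data = df, FUN = sum, na.action = NULL)
  xs <- agg(x[, c("event_id", "sample_id", "ratio")])
  ys <- agg(y[, c("event_id", "sample_id", "ratio")])
  m <- merge(xs, ys, by = c("event_id", "sample_id"),
             suffixes = c("_x", "_y"))
  ok <- stats::complete.cases(m[, c("ratio_x", "ratio_y")])
  m <- m[ok, ]
  if (nrow(m) < 3)
    stop("need at least 3 complete ratio pairs, got ", nrow(m))
  list(pearson = stats::cor(m$ratio_x, m$ratio_y, method = "pearson"),
       spearman = stats::cor(m$ratio_x, m$ratio_y, method = "spearman"),
       n = nrow(m))
}
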