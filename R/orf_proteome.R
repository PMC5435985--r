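#' Longest ATG-initiated open reading frame
#'
#' Scans every ATG of the sequence and translates in frame to the first stop
#' codon (or to the last complete codon when no stop is found). The longest
#' ORF wins; equal lengths are broken in favour of the 5'-most ATG.
#'
#' @param seq A transcript (mRNA) sequence, character scalar.
#' @return `NULL` when the sequence has no ATG, otherwise a list with
#'   `start` (1-based offset of the A), `length` (nucleotides, start through
#'   stop inclusive, always divisible by 3) and `ran_off_end` (TRUE when no
#'   in-frame stop was found).
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(NULL)
  best <- NULL
  for (s in as.integer(starts)) {
    if (s + 2L > n) next
    cod_starts <- seq.int(s, n - 2L, by = 3L)
    codons <- substring(seq, cod_starts, cod_starts + 2L)
    stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))[1]
    if (is.na(stop_i)) {
      len <- 3L * length(codons)
      ran <- TRUE
    } else {
      len <- 3L * stop_i
      ran <- FALSE
    }
    if (is.null(best) || len > best$length)
      best <- list(start = s, length = len, ran_off_end = ran)
  }
  best
}

# genomic position of every mRNA base, 5' to 3' in transcript orientation
mrna_genomic_positions <- function(exons) {
  pos <- unlist(mapply(seq.int, GenomicRanges::start(exons),
                       GenomicRanges::end(exons), SIMPLIFY = FALSE),
                use.names = FALSE)
  if (as.character(GenomicRanges::strand(exons))[1] == "-") pos <- rev(pos)
  pos
}

translate_codons <- function(seq, from) {
  n <- nchar(seq)
  len <- ((n - from + 1L) %/% 3L) * 3L
  if (len < 3L)
    return(list(protein = "", stop_status = "ran_off_end"))
  cod_starts <- seq.int(from, from + len - 3L, by = 3L)
  codons <- substring(seq, cod_starts, cod_starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_i <- which(aa == "*")[1]
  if (is.na(stop_i))
    list(protein = paste(aa, collapse = ""), stop_status = "ran_off_end")
  else
    list(protein = paste(aa[seq_len(stop_i - 1L)], collapse = ""),
         stop_status = "stop_found")
}

#' Select the translation-anchor AUG of a gene
#'
#' For every transcript of the gene, the longest ATG-initiated ORF is found;
#' the gene's anchor is the AUG of the transcript with the maximal ORF
#' length (ties: 5'-most AUG within the winning transcript, then
#' lexicographically smallest transcript id). The anchor is recorded as the
#' genomic coordinates of the three AUG bases, so mapping it into other
#' isoforms is splice-aware.
#'
#' @param x A transcriptome.
#' @param genome Genome from [read_genome()].
#' @param gene Optional single gene id; default all genes.
#' @return A data.frame with one row per gene: `gene_id`, `anchor_transcript`
#'   (NA when no transcript of the gene has an ATG), `orf_length`,
#'   `aug_pos1`, `aug_pos2`, `aug_pos3` (genomic coordinates of the AUG
#'   bases, in transcript order).
#' @export
select_anchor <- function(x, genome, gene = NULL) {
  seqs <- as.character(extract_sequences(x, genome))
  t2g <- tx2gene(x)
  genes <- if (is.null(gene)) unique(t2g$gene_id) else gene
  grl <- exons_by_transcript(x)
  out <- lapply(genes, function(g) {
    txs <- sort(t2g$transcript_id[t2g$gene_id == g])
    orfs <- lapply(txs, function(id) longest_orf(seqs[[id]]))
    has <- !vapply(orfs, is.null, logical(1))
    if (!any(has))
      return(data.frame(gene_id = g, anchor_transcript = NA_character_,
                        orf_length = NA_integer_, aug_pos1 = NA_integer_,
                        aug_pos2 = NA_integer_, aug_pos3 = NA_integer_,
                        stringsAsFactors = FALSE))
    lens <- vapply(orfs, function(o) if (is.null(o)) -1L else o$length,
                   integer(1))
    win <- which(lens == max(lens))[1]  # txs sorted: lexicographic tie-break
    o <- orfs[[win]]
    pos <- mrna_genomic_positions(grl[[txs[win]]])
    aug <- pos[o$start:(o$start + 2L)]
    data.frame(gene_id = g, anchor_transcript = txs[win],
               orf_length = o$length, aug_pos1 = aug[1], aug_pos2 = aug[2],
               aug_pos3 = aug[3], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Translate every transcript from its gene's fixed AUG
#'
#' Transcripts in which the anchor AUG's three genomic bases are exonic,
#' contiguous in the mRNA and spell ATG are translated from that point
#' (`mode = "anchored"`); transcripts that lost the anchor (e.g. through an
#' AS event) fall back to their own longest ATG-initiated ORF
#' (`mode = "fallback_longest_orf"`); transcripts without any ATG are
#' `untranslated`.
#'
#' @param x A transcriptome.
#' @param genome Genome from [read_genome()].
#' @return A list with `proteins` (an `AAStringSet` of the translated
#'   transcripts, no terminal stop symbol), `records` (a data.frame with
#'   `transcript_id`, `gene_id`, `mode`, `stop_status`, `protein_length`)
#'   and `anchors` (the [select_anchor()] table).
#' @export
translate_transcriptome <- function(x, genome) {
  seqs <- as.character(extract_sequences(x, genome))
  t2g <- tx2gene(x)
  grl <- exons_by_transcript(x)
  anchors <- select_anchor(x, genome)
  recs <- vector("list", nrow(t2g))
  prots <- character(0)
  for (i in seq_len(nrow(t2g))) {
    id <- t2g$transcript_id[i]
    g <- t2g$gene_id[i]
    a <- anchors[anchors$gene_id == g, ]
    res <- NULL
    mode <- "untranslated"
    if (!is.na(a$anchor_transcript)) {
      pos <- mrna_genomic_positions(grl[[id]])
      j <- match(a$aug_pos1, pos)
      if (!is.na(j) && j + 2L <= length(pos) &&
          pos[j + 1L] == a$aug_pos2 && pos[j + 2L] == a$aug_pos3 &&
          substr(seqs[[id]], j, j + 2L) == "ATG") {
        res <- translate_codons(seqs[[id]], j)
        mode <- "anchored"
      }
    }
    if (is.null(res)) {
      o <- longest_orf(seqs[[id]])
      if (!is.null(o)) {
        res <- translate_codons(seqs[[id]], o$start)
        mode <- "fallback_longest_orf"
      }
    }
    if (is.null(res)) {
      recs[[i]] <- data.frame(transcript_id = id, gene_id = g,
                              mode = "untranslated",
                              stop_status = NA_character_,
                              protein_length = 0L, stringsAsFactors = FALSE)
    } else {
      prots[id] <- res$protein
      recs[[i]] <- data.frame(transcript_id = id, gene_id = g, mode = mode,
                              stop_status = res$stop_status,
                              protein_length = nchar(res$protein),
                              stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  prots <- prots[nchar(prots) > 0]
  list(proteins = Biostrings::AAStringSet(prots), records = records,
       anchors = anchors)
}

#' Fallback translation: a transcript's own longest ORF
#'
#' @param seq Transcript (mRNA) sequence.
#' @return A list with `protein`, `stop_status` and `mode`
#'   (`"fallback_longest_orf"`), or `NULL` when the sequence has no ATG.
#' @export
translate_fallback <- function(seq) {
  o <- longest_orf(seq)
  if (is.null(o)) return(NULL)
  res <- translate_codons(seq, o$start)
  res$mode <- "fallback_longest_orf"
  res
}

#' In silico trypsin digestion
#'
#' Cleaves after every arginine or lysine that is not followed by a proline
#' (no missed cleavages) and keeps fragments of at least `min_len` residues.
#' Non-standard residues are retained and are never cleavage sites (with a
#' warning).
#'
#' @param proteins Character vector (or `AAStringSet`) of protein sequences.
#' @param min_len Minimum peptide length (default 7).
#' @return A list of character vectors of peptides, one element per protein.
#' @export
digest_trypsin <- function(proteins, min_len = 7) {
  if (methods::is(proteins, "AAStringSet")) {
    nm <- names(proteins)
    proteins <- stats::setNames(as.character(proteins), nm)
  }
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", proteins)))
    warning("non-standard residue(s) retained; they never act as cleavage ",
            "sites")
  lapply(proteins, function(p) {
    if (!nzchar(p)) stop("cannot digest an empty protein")
    frags <- strsplit(p, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
    frags[nchar(frags) >= min_len]
  })
}

#' Build a peptide-to-isoform uniqueness index
#'
#' Peptides are deduplicated globally and mapped back to every protein
#' isoform that contains them; a peptide is unique when it is associated
#' with exactly one transcript.
#'
#' @param peptides A named list of peptide vectors (one element per
#'   transcript), as returned by [digest_trypsin()].
#' @param tx2gene Optional data.frame mapping `transcript_id` to `gene_id`
#'   (for the gene-level summary).
#' @return A list with `index` (data.frame: `peptide`, `n_transcripts`,
#'   `transcript_ids` comma-separated, `unique`) and `summary` (total and
#'   unique peptide counts, the unique fraction, and the number of
#'   transcripts / genes with at least one unique peptide).
#' @export
build_peptide_index <- function(peptides, tx2gene = NULL) {
  if (is.null(names(peptides)) || any(!nzchar(names(peptides))))
    stop("'peptides' must be a named list (names = transcript ids)")
  tx <- rep(names(peptides), lengths(peptides))
  pep <- unlist(peptides, use.names = FALSE)
  pairs <- unique(data.frame(peptide = pep, transcript_id = tx,
                             stringsAsFactors = FALSE))
  sets <- tapply(pairs$transcript_id, pairs$peptide,
                 function(v) sort(unique(v)))
  index <- data.frame(
    peptide = names(sets),
    n_transcripts = lengths(sets),
    transcript_ids = vapply(sets, paste, character(1), collapse = ","),
    unique = lengths(sets) == 1L,
    stringsAsFactors = FALSE)
  rownames(index) <- NULL
  uniq_tx <- unique(unlist(sets[index$unique], use.names = FALSE))
  n_genes <- NA_integer_
  if (!is.null(tx2gene))
    n_genes <- length(unique(
      tx2gene$gene_id[tx2gene$transcript_id %in% uniq_tx]))
  summary <- list(
    n_peptides = nrow(index),
    n_unique = sum(index$unique),
    frac_unique = if (nrow(index)) sum(index$unique) / nrow(index) else NA,
    n_transcripts_with_unique = length(uniq_tx),
    n_genes_with_unique = n_genes)
  list(index = index, summary = summary)
}
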