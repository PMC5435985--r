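#' Read transcript models from a GTF file
#'
#' Only `exon` feature lines are used; every exon line must carry
#' `transcript_id` and `gene_id` attributes. GTF coordinates (1-based,
#' closed) are kept as such internally.
#'
#' @param path Path to a GTF file.
#' @param name Label for the resulting transcriptome.
#' @return A [transcriptome].
#' @export
read_gtf <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  content <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (any(content)) {
    nf <- lengths(strsplit(lines[content], "\t", fixed = TRUE))
    if (any(nf != 9)) {
      lineno <- which(content)[which(nf != 9)[1]]
      stop("malformed GTF line ", lineno, " in ", path,
           ": expected 9 tab-separated fields, found ", nf[nf != 9][1])
    }
  } else {
    return(empty_transcriptome(name))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "exon"]
  if (!length(gr)) return(empty_transcriptome(name))
  tid <- S4Vectors::mcols(gr)$transcript_id
  gid <- S4Vectors::mcols(gr)$gene_id
  if (is.null(tid) || anyNA(tid))
    stop("exon line without transcript_id attribute in ", path)
  if (is.null(gid) || anyNA(gid))
    stop("exon line without gene_id attribute in ", path)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcript_id = as.character(tid), gene_id = as.character(gid))
  transcriptome(gr, name = name)
}

#' Write a transcriptome as GTF
#'
#' Emits one `exon` line per exon with `gene_id` and `transcript_id`
#' attributes. `read_gtf(write_gtf(x, f))` reproduces `x`.
#'
#' @param x A transcriptome.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "rtdkit") {
  ex <- x$exons
  if (!length(ex)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    source = source,
    type = "exon",
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id))
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' Read a splice-junction table (STAR SJ.out.tab dialect)
#'
#' Nine tab-separated columns: chromosome, intron start and end (1-based
#' first and last intronic base), strand code (0 undetermined, 1 `+`, 2 `-`),
#' motif code, annotated flag, unique-read count, multi-read count, overhang.
#' Undetermined-strand junctions are kept with strand `"*"`; they can never
#' be classified canonical downstream.
#'
#' @param path Path to the junction table.
#' @param sample_id Sample identifier attached to every record.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `unique_reads`, `multi_reads`, `sample_id`.
#' @export
read_sj_tab <- function(path, sample_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      unique_reads = integer(0), multi_reads = integer(0),
                      sample_id = character(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    stop("line ", i, " of ", path, ": expected 9 tab-separated columns, ",
         "found ", nf[i])
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  code <- as.integer(m[, 4])
  if (anyNA(code) || any(!code %in% 0:2))
    stop("invalid strand code in ", path, " (must be 0, 1 or 2)")
  uniq <- as.integer(m[, 7])
  mult <- as.integer(m[, 8])
  if (anyNA(uniq) || anyNA(mult) || any(uniq < 0) || any(mult < 0))
    stop("read counts in ", path, " must be non-negative integers")
  data.frame(chrom = m[, 1],
             start = as.integer(m[, 2]),
             end = as.integer(m[, 3]),
             strand = c("*", "+", "-")[code + 1L],
             unique_reads = uniq,
             multi_reads = mult,
             sample_id = sample_id,
             stringsAsFactors = FALSE)
}

#' Read transcript quantifications (salmon quant.sf dialect)
#'
#' Each file must have the header `Name Length EffectiveLength TPM NumReads`.
#' The TPM matrix is built over the union of transcript ids; a transcript
#' absent from a sample's file gets TPM 0 with a warning.
#'
#' @param paths Character vector of quant.sf paths.
#' @param sample_ids Sample identifiers, same length as `paths`.
#' @return A numeric matrix of TPM values (transcripts x samples).
#' @export
read_quant <- function(paths, sample_ids) {
  if (length(paths) != length(sample_ids))
    stop("'paths' and 'sample_ids' must have the same length")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample_ids")
  want <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  tabs <- lapply(seq_along(paths), function(i) {
    df <- utils::read.delim(paths[i], stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!identical(names(df), want))
      stop("unexpected header in ", paths[i], ": expected '",
           paste(want, collapse = " "), "'")
    if (any(df$TPM < 0)) stop("negative TPM in ", paths[i])
    df
  })
  ids <- sort(unique(unlist(lapply(tabs, `[[`, "Name"))))
  tpm <- matrix(0, nrow = length(ids), ncol = length(paths),
                dimnames = list(ids, sample_ids))
  n_missing <- 0L
  for (j in seq_along(tabs)) {
    tpm[tabs[[j]]$Name, j] <- tabs[[j]]$TPM
    n_missing <- n_missing + (length(ids) - nrow(tabs[[j]]))
  }
  if (n_missing > 0)
    warning(n_missing, " (transcript, sample) cell(s) missing from input; ",
            "TPM set to 0")
  tpm
}

#' Load a genome from FASTA
#'
#' @param path Path to a FASTA file with unique record ids (text up to the
#'   first whitespace of each header).
#' @return An object of class `"genome_seq"` supporting [fetch_seq()].
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicated sequence ids in ", path)
  structure(list(seq = seqs), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %d sequence(s), %s bp total\n",
              length(x$seq), format(sum(Biostrings::width(x$seq)),
                                    big.mark = ",")))
  invisible(x)
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    return(structure(list(seq = genome), class = "genome_seq"))
  if (!inherits(genome, "genome_seq"))
    stop("'genome' must be a genome_seq (see read_genome) or DNAStringSet")
  genome
}

#' Chromosome lengths of a genome
#'
#' @param genome A genome from [read_genome()].
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  genome <- as_genome(genome)
  stats::setNames(Biostrings::width(genome$seq), names(genome$seq))
}

#' Fetch genomic sequence
#'
#' Returns the uppercase sequence of `[start, end]` (1-based, closed) on
#' `chrom`, reverse-complemented when `strand == "-"` so the result always
#' reads 5' to 3' in transcript orientation.
#'
#' @param genome A genome from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 1-based closed coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar.
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome$seq))
    stop("unknown chromosome: ", chrom)
  len <- length(genome$seq[[chrom]])
  if (start < 1 || end > len || start > end)
    stop("coordinates [", start, ", ", end, "] out of range for ", chrom,
         " (length ", len, ")")
  s <- Biostrings::subseq(genome$seq[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}
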