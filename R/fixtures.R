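#' Specification for the synthetic data generator
#'
#' Defines the study conditions emulated by [simulate_rtd()]: a toy genome
#' of multi-exon genes with alternatively spliced isoforms, mis-assembled
#' isoforms carrying non-canonical or poorly supported junctions, antisense
#' fragments, transcripts from unknown loci, redundant UTR-variant twins and
#' low-expression isoforms, together with per-sample junction support,
#' transcript TPMs consistent with known AS/FS ratios, and experimental
#' peak-area measurements of the same ratios.
#'
#' @param seed Master seed; one derived stream per file type, so adding a
#'   file type never perturbs existing ones.
#' @param n_genes,n_samples Number of genes and samples.
#' @param isoforms_per_gene Range (min, max) of isoforms per gene, the fully
#'   spliced form included; extras become AS isoforms.
#' @param n_exons Range of exon counts per gene (min 3).
#' @param exon_length Nominal exon length range; lengths are actually drawn
#'   per part (UTRs and coding pieces, see the methods vignette) so that
#'   coding frames stay intact, and land inside this range.
#' @param intron_length Intron length range (nt); at least 33 so introns can
#'   host the splice-site windows and 12 nt alternative-boundary insertions.
#' @param frac_ir,frac_alt5,frac_alt3,frac_es Relative frequencies of event
#'   types among AS isoforms (intron retention most common, then Alt3, Alt5,
#'   exon skipping).
#' @param frac_noncanonical,frac_unsupported Fractions of genes carrying one
#'   mis-assembled isoform whose novel junction is non-canonical /
#'   canonical-but-unsupported.
#' @param frac_lowexpr,frac_antisense,frac_unknown,frac_rescue,frac_redundant
#'   Fractions of genes carrying, respectively: a low-expression isoform, an
#'   antisense fragment contained in the gene, a transcript from an unknown
#'   intergenic locus, a novel-gene-id isoform rescuable by exon overlap,
#'   and a redundant UTR-variant twin. Roles are assigned to disjoint gene
#'   subsets so every transcript has exactly one expected fate.
#' @param support_mean Mean unique-read count for supported junctions.
#' @param low_support_max Maximum unique reads per sample for designated
#'   unsupported junctions (below the 10-read support threshold).
#' @param gene_tpm Range of per-gene total TPM per sample.
#' @param dirichlet_conc Concentration of the Dirichlet split of gene
#'   expression across isoforms (drawn per sample).
#' @param lowexpr_max_tpm Upper TPM bound for designated low-expression
#'   isoforms (below the TPM > 1 rule in every sample).
#' @param peak_fs_area,peak_dispersion Fully spliced product peak-area scale
#'   and the log-normal noise s.d. of AS peak areas around the true ratio.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 200L, n_samples = 8L,
                         isoforms_per_gene = c(1L, 3L),
                         n_exons = c(3L, 5L),
                         exon_length = c(90L, 240L),
                         intron_length = c(60L, 120L),
                         frac_ir = 0.40, frac_alt5 = 0.20, frac_alt3 = 0.25,
                         frac_es = 0.15,
                         frac_noncanonical = 0.06, frac_unsupported = 0.06,
                         frac_lowexpr = 0.08, frac_antisense = 0.05,
                         frac_unknown = 0.05, frac_rescue = 0.05,
                         frac_redundant = 0.08,
                         support_mean = 30, low_support_max = 9L,
                         gene_tpm = c(20, 200), dirichlet_conc = 8,
                         lowexpr_max_tpm = 0.9,
                         peak_fs_area = 5000, peak_dispersion = 0.15) {
  fr <- c(frac_ir, frac_alt5, frac_alt3, frac_es, frac_noncanonical,
          frac_unsupported, frac_lowexpr, frac_antisense, frac_unknown,
          frac_rescue, frac_redundant)
  stopifnot(all(fr >= 0), all(fr <= 1), n_genes >= 1, n_samples >= 3,
            n_exons[1] >= 3, intron_length[1] >= 33,
            isoforms_per_gene[1] >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("<fixture_spec> seed %d: %d genes x %d samples\n",
              x$seed, x$n_genes, x$n_samples))
  invisible(x)
}

# --- sequence helpers ------------------------------------------------------

fx_bases <- c("A", "C", "G", "T")

fx_rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(fx_bases, n, replace = TRUE), collapse = "")
}

# remove every ATG by mutating its T to C (cannot create ATG or stop codons)
fx_scrub_atg <- function(s) {
  repeat {
    i <- regexpr("ATG", s, fixed = TRUE)
    if (i < 0) return(s)
    substr(s, i + 1L, i + 1L) <- "C"
  }
}

fx_safe_codons <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      all <- as.vector(outer(outer(fx_bases, fx_bases, paste0), fx_bases,
                             paste0))
      memo <<- setdiff(all, c("ATG", "TAA", "TAG", "TGA"))
    }
    memo
  }
})

fx_rand_cds <- function(ncod) {
  paste(sample(fx_safe_codons(), ncod, replace = TRUE), collapse = "")
}

fx_sample_site <- function(consensus, p = 0.85, fixed = integer(0)) {
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  out <- vapply(seq_along(ch), function(i) {
    if (i %in% fixed || stats::runif(1) < p) ch[i]
    else sample(setdiff(fx_bases, ch[i]), 1)
  }, character(1))
  paste(out, collapse = "")
}

fx_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# independent ORF scan used for ground-truth anchors: frame-wise stop
# bookkeeping rather than the per-ATG codon walk of longest_orf()
fx_longest_orf <- function(seq) {
  n <- nchar(seq)
  atgs <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (atgs[1] == -1L) return(NULL)
  best <- NULL
  for (frame in 0:2) {
    if (frame + 3L > n) next
    cs <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(seq, cs, cs + 2L)
    stops <- cs[codons %in% c("TAA", "TAG", "TGA")]
    f_atgs <- atgs[(atgs - 1L) %% 3L == frame]
    for (a in as.integer(f_atgs)) {
      nxt <- stops[stops > a]
      len <- if (length(nxt)) nxt[1] + 2L - a + 1L
             else 3L * sum(cs >= a)
      if (is.null(best) || len > best$length ||
          (len == best$length && a < best$start))
        best <- list(start = a, length = as.integer(len))
    }
  }
  best
}

# map an interval in gene-offset space (1..L, transcript orientation) to
# genomic coordinates; B = genomic start of the gene block
fx_map_iv <- function(a, b, strand, B, L) {
  if (strand == "+") c(B + a - 1L, B + b - 1L)
  else c(B + L - b, B + L - a)
}

# --- generator -------------------------------------------------------------

#' Generate a synthetic RTD test data set
#'
#' Writes a toy genome (FASTA), a transcript-assembly annotation and a
#' reference annotation (GTF), per-sample splice-junction tables
#' (SJ.out.tab dialect) and transcript quantifications (quant.sf dialect),
#' and an experimental peak-area table, all consistent by construction with
#' the returned ground truth: per-junction canonical/support status,
#' per-transcript filter fate, per-gene anchor AUG position, and per-event
#' AS/FS splicing ratios per sample. Identical seeds give identical files.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `spec`, `samples`, `files` (paths: genome,
#'   assembly_gtf, reference_gtf, sj, quant, peaks) and `truth` (data frames
#'   `junctions`, `fates`, `anchors`, `events`, `ratios`).
#' @export
simulate_rtd <- function(spec = fixture_spec(), outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 5)
  samples <- sprintf("s%02d", seq_len(spec$n_samples))

  genes <- fx_structures(spec, streams[1])
  genes <- fx_sequences(spec, genes, streams[2])
  genes <- fx_isoforms(genes)
  layout <- fx_layout(genes)
  genes <- layout$genes

  ann <- fx_annotation_tables(genes)
  truth_junc <- fx_junction_truth(genes)
  anchors <- fx_anchor_truth(genes)

  # write genome + annotations
  genome_fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(layout$chrom_seq), genome_fa)
  assembly_gtf <- file.path(outdir, "assembly.gtf")
  write_gtf(transcriptome(ann$assembly, name = "assembly"), assembly_gtf)
  reference_gtf <- file.path(outdir, "reference.gtf")
  write_gtf(transcriptome(ann$reference, name = "reference"), reference_gtf)

  # stream 3: per-sample junction support
  set.seed(streams[3])
  sj_dir <- file.path(outdir, "sj")
  dir.create(sj_dir, showWarnings = FALSE)
  nj <- nrow(truth_junc)
  counts <- matrix(0L, nj, spec$n_samples,
                   dimnames = list(truth_junc$junction_key, samples))
  for (i in seq_len(nj)) {
    counts[i, ] <- if (truth_junc$supported[i])
      10L + stats::rpois(spec$n_samples, spec$support_mean - 10)
    else
      sample(0:spec$low_support_max, spec$n_samples, replace = TRUE)
  }
  sj_files <- stats::setNames(file.path(sj_dir, paste0(samples, ".tab")),
                              samples)
  ord <- order(truth_junc$chrom, truth_junc$start, truth_junc$end)
  for (s in samples) {
    df <- data.frame(truth_junc$chrom, truth_junc$start, truth_junc$end,
                     ifelse(truth_junc$strand == "+", 1L, 2L),
                     ifelse(truth_junc$canonical, 1L, 0L), 1L,
                     counts[, s], pmax(0L, counts[, s] %/% 10L), 20L)[ord, ]
    utils::write.table(df, sj_files[s], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }

  # stream 4: transcript quantifications
  set.seed(streams[4])
  tpm <- fx_tpm(spec, genes, samples)
  quant_dir <- file.path(outdir, "quant")
  dir.create(quant_dir, showWarnings = FALSE)
  quant_files <- stats::setNames(
    file.path(quant_dir, paste0(samples, ".sf")), samples)
  lens <- fx_mrna_lengths(genes)
  for (s in samples) {
    df <- data.frame(Name = rownames(tpm),
                     Length = lens[rownames(tpm)],
                     EffectiveLength = pmax(lens[rownames(tpm)] - 200L, 1L),
                     TPM = sprintf("%.4f", tpm[, s]),
                     NumReads = round(tpm[, s] * 20))
    utils::write.table(df, quant_files[s], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tpm <- round(tpm, 4)  # exactly the values a reader recovers

  events <- fx_event_truth(genes)
  ratios <- fx_ratio_truth(events, tpm, samples)

  # stream 5: experimental peak areas
  set.seed(streams[5])
  peaks <- NULL
  if (nrow(events)) {
    rows <- vector("list", nrow(events) * length(samples))
    r <- 0L
    for (i in seq_len(nrow(events))) {
      for (s in samples) {
        fs_area <- spec$peak_fs_area * exp(stats::rnorm(1, 0, 0.3))
        tr <- ratios$ratio[ratios$event_id == events$event_id[i] &
                             ratios$sample_id == s]
        as_area <- tr * fs_area * exp(stats::rnorm(1, 0,
                                                   spec$peak_dispersion))
        r <- r + 1L
        rows[[r]] <- data.frame(
          gene_id = events$gene_id[i], event_id = events$event_id[i],
          product_label = c("FS", "AS1"), sample_id = s,
          peak_area = round(c(fs_area, as_area), 3),
          stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, rows)
  } else {
    peaks <- data.frame(gene_id = character(0), event_id = character(0),
                        product_label = character(0),
                        sample_id = character(0), peak_area = numeric(0))
  }
  peaks_file <- file.path(outdir, "peak_areas.tsv")
  utils::write.table(peaks, peaks_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  fates <- fx_fate_truth(genes)
  truth <- list(junctions = truth_junc, fates = fates, anchors = anchors,
                events = events, ratios = ratios)
  for (nm in names(truth))
    utils::write.table(truth[[nm]],
                       file.path(outdir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(spec = spec, samples = samples,
                 files = list(genome = genome_fa,
                              assembly_gtf = assembly_gtf,
                              reference_gtf = reference_gtf,
                              sj = sj_files, quant = quant_files,
                              peaks = peaks_file),
                 truth = truth))
}

# -- stage 1: gene structures and roles ------------------------------------
fx_structures <- function(spec, stream_seed) {
  set.seed(stream_seed)
  ng <- spec$n_genes
  roles <- rep("none", ng)
  pool <- sample.int(ng)
  take <- function(frac) {
    k <- round(frac * ng)
    out <- utils::head(pool, k)
    pool <<- utils::tail(pool, max(0L, length(pool) - k))
    out
  }
  roles[take(spec$frac_noncanonical)] <- "noncanonical"
  roles[take(spec$frac_unsupported)] <- "unsupported"
  roles[take(spec$frac_lowexpr)] <- "lowexpr"
  roles[take(spec$frac_antisense)] <- "antisense"
  roles[take(spec$frac_unknown)] <- "unknown"
  roles[take(spec$frac_rescue)] <- "rescue"
  roles[take(spec$frac_redundant)] <- "redundant"

  ev_types <- c("IR", "Alt5", "Alt3", "ES")
  ev_prob <- c(spec$frac_ir, spec$frac_alt5, spec$frac_alt3, spec$frac_es)
  ev_prob <- ev_prob / sum(ev_prob)

  lapply(seq_len(ng), function(g) {
    n_ex <- sample(spec$n_exons[1]:spec$n_exons[2], 1)
    u5 <- sample(36:60, 1)
    c1 <- 3L * sample(12:25, 1)
    internal <- if (n_ex > 2) 3L * sample(30:78, n_ex - 2, replace = TRUE)
                else integer(0)
    clast <- 3L * sample(12:25, 1)
    u3 <- sample(36:60, 1)
    ex_len <- c(u5 + c1, internal, clast + u3)
    in_len <- sample(spec$intron_length[1]:spec$intron_length[2],
                     n_ex - 1, replace = TRUE)
    # AS events live on introns 2..n_ex-1; intron 1 is reserved for
    # mis-assembly / low-expression / rescue artefacts
    free <- setdiff(seq_len(n_ex - 1L), 1L)
    n_extra <- sample(spec$isoforms_per_gene[1]:spec$isoforms_per_gene[2],
                      1) - 1L
    events <- list()
    for (e in seq_len(n_extra)) {
      if (!length(free)) break
      ty <- sample(ev_types, 1, prob = ev_prob)
      if (ty == "ES") {
        cand <- free[free <= n_ex - 2L & (free + 1L) %in% free]
        if (length(cand)) {
          k <- if (length(cand) == 1) cand else sample(cand, 1)
          events[[length(events) + 1L]] <- list(type = "ES", k = k)
          free <- setdiff(free, c(k, k + 1L))
          next
        }
        ty <- "IR"
      }
      k <- if (length(free) == 1) free else sample(free, 1)
      events[[length(events) + 1L]] <- list(type = ty, k = k)
      free <- setdiff(free, k)
    }
    list(gene_id = sprintf("G%04d", g),
         chrom = paste0("chr", (g - 1L) %% 2L + 1L),
         strand = sample(c("+", "-"), 1),
         n_ex = n_ex, u5 = u5, c1 = c1, clast = clast, u3 = u3,
         ex_len = ex_len, in_len = in_len,
         role = roles[g], events = events)
  })
}

# -- stage 2: sequences -----------------------------------------------------
fx_alt5_ins <- "GTTCTTGCTGGT"  # starts GT (FS donor); no ATG, no stop codon
fx_alt3_ins <- "GCTGCTGCTGAG"  # ends AG (FS acceptor); no ATG, no stop

fx_sequences <- function(spec, genes, stream_seed) {
  set.seed(stream_seed)
  for (g in seq_along(genes)) {
    gn <- genes[[g]]
    n_ex <- gn$n_ex
    cds_len <- gn$c1 + (if (n_ex > 2) sum(gn$ex_len[2:(n_ex - 1)]) else 0L) +
      gn$clast
    ncod <- cds_len %/% 3L
    mrna <- paste0(fx_scrub_atg(fx_rand_dna(gn$u5)),
                   "ATG", fx_rand_cds(ncod - 2L), "TAA",
                   fx_rand_dna(gn$u3))
    offs_e <- cumsum(gn$ex_len)
    offs_s <- offs_e - gn$ex_len + 1L
    ex_seq <- substring(mrna, offs_s, offs_e)
    ev_type_of <- rep(NA_character_, n_ex - 1L)
    for (e in gn$events) ev_type_of[e$k] <- e$type
    in_seq <- character(n_ex - 1L)
    for (k in seq_len(n_ex - 1L)) {
      ilen <- gn$in_len[k]
      donor <- fx_sample_site("GTAAGTATTT", fixed = 1:2)
      acceptor <- fx_sample_site("TTTTTTGCAG", fixed = 9:10)
      if (k == 1L && gn$role == "unsupported")
        donor <- "GTAGTAAGTA"  # a +3 shift still starts with a GT donor
      ty <- ev_type_of[k]
      in_seq[k] <- if (!is.na(ty) && ty == "Alt5")
        paste0(fx_alt5_ins, donor, fx_rand_dna(ilen - 32L), acceptor)
      else if (!is.na(ty) && ty == "Alt3")
        paste0(donor, fx_rand_dna(ilen - 32L), acceptor, fx_alt3_ins)
      else
        paste0(donor, fx_rand_dna(ilen - 20L), acceptor)
      stopifnot(nchar(in_seq[k]) == ilen)
    }
    parts <- character(0)
    for (k in seq_len(n_ex)) {
      parts <- c(parts, ex_seq[k])
      if (k < n_ex) parts <- c(parts, in_seq[k])
    }
    gn$gene_seq <- paste(parts, collapse = "")
    # offset bookkeeping
    cur <- 0L
    ex_s <- ex_e <- integer(n_ex)
    in_s <- in_e <- integer(max(0L, n_ex - 1L))
    for (k in seq_len(n_ex)) {
      ex_s[k] <- cur + 1L
      cur <- cur + gn$ex_len[k]
      ex_e[k] <- cur
      if (k < n_ex) {
        in_s[k] <- cur + 1L
        cur <- cur + gn$in_len[k]
        in_e[k] <- cur
      }
    }
    gn$ex_s <- ex_s; gn$ex_e <- ex_e
    gn$in_s <- in_s; gn$in_e <- in_e
    gn$L <- cur
    stopifnot(cur == nchar(gn$gene_seq))
    # pre-draw geometry randomness used later by the layout stage
    gn$gap <- sample(450:800, 1)
    genes[[g]] <- gn
  }
  genes
}

# -- stage 3: isoform structures in offset space ---------------------------
fx_isoforms <- function(genes) {
  for (g in seq_along(genes)) {
    gn <- genes[[g]]
    n_ex <- gn$n_ex
    fs <- data.frame(start = gn$ex_s, end = gn$ex_e)
    iso <- list()
    add_iso <- function(suffix, structure, fate, gene_id = gn$gene_id,
                        tpm_class = "normal", event = NULL,
                        reassigned_to = NA_character_, kept_as =
                          NA_character_) {
      iso[[length(iso) + 1L]] <<- list(
        id = paste0(gn$gene_id, ".", suffix), gene_id = gene_id,
        structure = structure, fate = fate, tpm_class = tpm_class,
        event = event, reassigned_to = reassigned_to, kept_as = kept_as)
    }
    merge_exons <- function(df, k) {  # intron-retention of intron k
      out <- df
      out$end[k] <- out$end[k + 1L]
      out[-(k + 1L), , drop = FALSE]
    }
    add_iso("t1", fs, "kept")
    for (i in seq_along(gn$events)) {
      e <- gn$events[[i]]
      k <- e$k
      st <- fs
      ev_iv <- switch(e$type,
        IR = {
          st <- merge_exons(fs, k)
          c(gn$in_s[k], gn$in_e[k])
        },
        Alt5 = {
          st$end[k] <- st$end[k] + 12L
          c(gn$in_s[k], gn$in_s[k] + 11L)
        },
        Alt3 = {
          st$start[k + 1L] <- st$start[k + 1L] - 12L
          c(gn$in_e[k] - 11L, gn$in_e[k])
        },
        ES = {
          st <- fs[-(k + 1L), , drop = FALSE]
          c(gn$ex_s[k + 1L], gn$ex_e[k + 1L])
        })
      add_iso(paste0("as", i), st, "kept",
              event = list(type = e$type, iv = ev_iv))
    }
    if (gn$role == "noncanonical") {
      st <- fs; st$end[1] <- st$end[1] + 1L
      add_iso("nc1", st, "non_canonical_junction", tpm_class = "artifact")
    }
    if (gn$role == "unsupported") {
      st <- fs; st$end[1] <- st$end[1] + 3L
      add_iso("ns1", st, "unsupported_junction", tpm_class = "artifact")
    }
    if (gn$role == "lowexpr")
      add_iso("le1", merge_exons(fs, 1L), "low_expression",
              tpm_class = "low")
    if (gn$role == "rescue")
      add_iso("nv1", merge_exons(fs, 1L), "kept",
              gene_id = paste0("NOVG_", gn$gene_id),
              event = list(type = "IR", iv = c(gn$in_s[1], gn$in_e[1])),
              reassigned_to = gn$gene_id)
    if (gn$role == "redundant") {
      st <- fs; st$start[1] <- st$start[1] + 30L
      add_iso("tw1", st, "redundant", tpm_class = "artifact",
              kept_as = paste0(gn$gene_id, ".t1"))
    }
    gn$iso <- iso
    genes[[g]] <- gn
  }
  genes
}

# -- stage 4: genomic layout ------------------------------------------------
fx_layout <- function(genes) {
  chroms <- unique(vapply(genes, `[[`, character(1), "chrom"))
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  seq_parts <- stats::setNames(vector("list", length(chroms)), chroms)
  for (g in seq_along(genes)) {
    gn <- genes[[g]]
    ch <- gn$chrom
    gap <- gn$gap
    gap_start <- cursor[ch] + 1L
    B <- cursor[ch] + gap + 1L
    gap_seq <- fx_rand_dna(gap)
    block <- if (gn$strand == "+") gn$gene_seq else fx_revcomp(gn$gene_seq)
    seq_parts[[ch]] <- c(seq_parts[[ch]], gap_seq, block)
    cursor[ch] <- B + gn$L - 1L
    gn$B <- B
    gn$gap_start <- gap_start
    # genomic exon structures per isoform
    for (i in seq_along(gn$iso)) {
      st <- gn$iso[[i]]$structure
      giv <- t(vapply(seq_len(nrow(st)), function(r)
        fx_map_iv(st$start[r], st$end[r], gn$strand, B, gn$L),
        integer(2)))
      gdf <- data.frame(start = giv[, 1], end = giv[, 2])
      gdf <- gdf[order(gdf$start), , drop = FALSE]
      gn$iso[[i]]$gexons <- gdf
    }
    # role-attached extra records with direct genomic coordinates
    if (gn$role == "antisense")
      gn$extra <- list(id = paste0("ANTI_", gn$gene_id, ".t1"),
                       gene_id = paste0("ANTG_", gn$gene_id),
                       chrom = ch,
                       strand = if (gn$strand == "+") "-" else "+",
                       start = B + 10L,
                       end = B + min(300L, gn$L - 20L),
                       fate = "antisense_contained")
    if (gn$role == "unknown")
      gn$extra <- list(id = paste0("UNK_", gn$gene_id, ".t1"),
                       gene_id = paste0("UNKG_", gn$gene_id),
                       chrom = ch, strand = "+",
                       start = gap_start + 50L,
                       end = gap_start + 349L,
                       fate = "unknown_gene")
    genes[[g]] <- gn
  }
  chrom_seq <- vapply(seq_parts, paste, character(1), collapse = "")
  list(genes = genes, chrom_seq = chrom_seq)
}

# -- derived tables ---------------------------------------------------------

fx_annotation_tables <- function(genes) {
  asm <- list()
  ref <- list()
  for (gn in genes) {
    for (iso in gn$iso)
      asm[[length(asm) + 1L]] <- data.frame(
        chrom = gn$chrom, start = iso$gexons$start, end = iso$gexons$end,
        strand = gn$strand, transcript_id = iso$id, gene_id = iso$gene_id,
        stringsAsFactors = FALSE)
    if (!is.null(gn$extra))
      asm[[length(asm) + 1L]] <- data.frame(
        chrom = gn$extra$chrom, start = gn$extra$start, end = gn$extra$end,
        strand = gn$extra$strand, transcript_id = gn$extra$id,
        gene_id = gn$extra$gene_id, stringsAsFactors = FALSE)
    fs <- gn$iso[[1]]
    ref[[length(ref) + 1L]] <- data.frame(
      chrom = gn$chrom, start = fs$gexons$start, end = fs$gexons$end,
      strand = gn$strand, transcript_id = paste0(gn$gene_id, ".r1"),
      gene_id = gn$gene_id, stringsAsFactors = FALSE)
  }
  list(assembly = do.call(rbind, asm), reference = do.call(rbind, ref))
}

# genomic junctions of one isoform (from its sorted genomic exons)
fx_iso_junctions <- function(gexons) {
  n <- nrow(gexons)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = gexons$end[-n] + 1L, end = gexons$start[-1] - 1L)
}

fx_junction_truth <- function(genes) {
  rows <- list()
  bad_nc_keys <- character(0)
  bad_ns_keys <- character(0)
  for (gn in genes) {
    for (iso in gn$iso) {
      j <- fx_iso_junctions(iso$gexons)
      if (!nrow(j)) next
      # the designated bad junction is the mis-assembled isoform's first
      # offset-space gap, mapped to genomic coordinates
      if (iso$fate %in% c("non_canonical_junction",
                          "unsupported_junction")) {
        st <- iso$structure
        gap1 <- fx_map_iv(st$end[1] + 1L, st$start[2] - 1L, gn$strand,
                          gn$B, gn$L)
        bad <- junction_key(gn$chrom, gn$strand, gap1[1], gap1[2])
        if (iso$fate == "non_canonical_junction")
          bad_nc_keys <- c(bad_nc_keys, bad)
        else
          bad_ns_keys <- c(bad_ns_keys, bad)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = gn$chrom, strand = gn$strand, start = j$start, end = j$end,
        junction_key = junction_key(gn$chrom, gn$strand, j$start, j$end),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$junction_key), ]
  df$canonical <- !df$junction_key %in% bad_nc_keys
  df$supported <- !df$junction_key %in% bad_ns_keys
  df$pass <- df$canonical & df$supported
  rownames(df) <- NULL
  df
}

fx_kept_iso <- function(gn) {
  Filter(function(iso) iso$fate == "kept", gn$iso)
}

fx_iso_mrna <- function(gn, iso) {
  st <- iso$structure
  paste(substring(gn$gene_seq, st$start, st$end), collapse = "")
}

fx_mrna_lengths <- function(genes) {
  out <- integer(0)
  for (gn in genes) {
    for (iso in gn$iso)
      out[iso$id] <- sum(iso$structure$end - iso$structure$start + 1L)
    if (!is.null(gn$extra))
      out[gn$extra$id] <- gn$extra$end - gn$extra$start + 1L
  }
  out
}

fx_anchor_truth <- function(genes) {
  rows <- lapply(genes, function(gn) {
    kept <- fx_kept_iso(gn)
    ids <- vapply(kept, `[[`, character(1), "id")
    o <- order(ids)
    kept <- kept[o]; ids <- ids[o]
    best <- NULL; best_id <- NA_character_; best_off <- NA_integer_
    for (i in seq_along(kept)) {
      orf <- fx_longest_orf(fx_iso_mrna(gn, kept[[i]]))
      if (is.null(orf)) next
      if (is.null(best) || orf$length > best$length) {
        best <- orf; best_id <- ids[i]
        st <- kept[[i]]$structure
        # mRNA offset -> gene offset
        w <- st$end - st$start + 1L
        cum <- cumsum(w)
        r <- which(orf$start <= cum)[1]
        prev <- if (r > 1) cum[r - 1L] else 0L
        best_off <- st$start[r] + (orf$start - prev) - 1L
      }
    }
    aug_pos <- if (is.na(best_id)) NA_integer_
    else fx_map_iv(best_off, best_off, gn$strand, gn$B, gn$L)[
      if (gn$strand == "+") 1L else 2L]
    data.frame(gene_id = gn$gene_id, anchor_transcript = best_id,
               orf_length = if (is.null(best)) NA_integer_ else best$length,
               aug_pos = aug_pos, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

fx_event_truth <- function(genes) {
  rows <- list()
  for (gn in genes) {
    kept_ids <- vapply(fx_kept_iso(gn), `[[`, character(1), "id")
    for (iso in gn$iso) {
      if (is.null(iso$event)) next
      iv <- fx_map_iv(iso$event$iv[1], iso$event$iv[2], gn$strand, gn$B,
                      gn$L)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = as_event_id(gn$gene_id, iso$event$type, gn$chrom,
                               iv[1], iv[2]),
        gene_id = gn$gene_id, type = iso$event$type, chrom = gn$chrom,
        strand = gn$strand, start = iv[1], end = iv[2],
        as_ids = iso$id,
        fs_ids = paste(sort(setdiff(kept_ids, iso$id)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), as_ids = character(0),
                      fs_ids = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$gene_id, df$start, df$type), ]
  rownames(df) <- NULL
  df
}

fx_tpm <- function(spec, genes, samples) {
  ids <- names(fx_mrna_lengths(genes))
  tpm <- matrix(0, length(ids), length(samples),
                dimnames = list(ids, samples))
  for (gn in genes) {
    kept <- vapply(fx_kept_iso(gn), `[[`, character(1), "id")
    for (s in samples) {
      total <- stats::runif(1, spec$gene_tpm[1], spec$gene_tpm[2])
      p <- stats::rgamma(length(kept), spec$dirichlet_conc)
      p <- p / sum(p)
      p <- pmax(p, 0.12)
      p <- p / sum(p)
      tpm[kept, s] <- total * p
    }
    for (iso in gn$iso) {
      if (iso$tpm_class == "low")
        tpm[iso$id, ] <- stats::runif(length(samples), 0,
                                      spec$lowexpr_max_tpm)
      else if (iso$tpm_class == "artifact")
        tpm[iso$id, ] <- stats::runif(length(samples), 2, 10)
    }
    if (!is.null(gn$extra))
      tpm[gn$extra$id, ] <- stats::runif(length(samples), 2, 10)
  }
  tpm
}

fx_ratio_truth <- function(events, tpm, samples) {
  if (!nrow(events))
    return(data.frame(event_id = character(0), sample_id = character(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    as_set <- strsplit(events$as_ids[i], ",", fixed = TRUE)[[1]]
    fs_set <- strsplit(events$fs_ids[i], ",", fixed = TRUE)[[1]]
    rows[[i]] <- data.frame(
      event_id = events$event_id[i], sample_id = samples,
      ratio = unname(colSums(tpm[as_set, , drop = FALSE]) /
                       colSums(tpm[fs_set, , drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

fx_fate_truth <- function(genes) {
  rows <- list()
  for (gn in genes) {
    for (iso in gn$iso)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = iso$id, gene_id = iso$gene_id, fate = iso$fate,
        reassigned_to = iso$reassigned_to,
        kept_as = iso$kept_as, stringsAsFactors = FALSE)
    if (!is.null(gn$extra))
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = gn$extra$id, gene_id = gn$extra$gene_id,
        fate = gn$extra$fate, reassigned_to = NA_character_,
        kept_as = NA_character_, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
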