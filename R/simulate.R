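## Synthetic-data generator. Emulates the study design: two groups
## (control / SAH) of pooled bulk RNA-seq samples (3 per group by default,
## each pool of 3 mice sequenced as one sample), negative-binomial
## (Gamma-Poisson) transcript counts with per-sample library-size factors,
## a planted fraction of differentially expressed transcripts with known
## log2 fold changes, and planted lncRNA-mRNA pairs whose log-scale
## expression shares a latent factor scaled to a target Pearson
## correlation. All outputs are pure functions of the configuration
## (including its seed).

#' Simulation configuration
#'
#' Defaults state the world the analysis assumes: 3 pooled samples per
#' group, moderately over-dispersed counts (NB dispersion 0.05), 20% of
#' transcripts differentially expressed with |log2FC| in \[2, 4\], and 10
#' planted lncRNA-mRNA pairs with target correlation 0.99 across samples.
#' `mean_log_expression` is the mean of the per-transcript log2 baseline
#' (log2 scale; 6 corresponds to ~64 expected counts at unit size factor).
#'
#' @param seed Integer seed; all generator output is a pure function of the
#'   config including this seed.
#' @param n_mrna,n_lncrna_known,n_lncrna_novel Transcript counts per class.
#' @param samples_per_group Pooled samples per group (>= 2; default 3).
#' @param mean_log_expression Mean log2 baseline expression.
#' @param sd_log_expression SD of the log2 baseline across transcripts.
#' @param nb_dispersion Negative-binomial dispersion (> 0; the Gamma-Poisson
#'   `size` is `1/nb_dispersion`). Values below 1e-8 fall back to Poisson.
#' @param de_fraction Fraction of transcripts with planted fold changes.
#' @param de_log2fc_range Range of planted |log2FC| (uniform; sign random).
#' @param n_planted_pairs Number of planted correlated lncRNA-mRNA pairs.
#' @param planted_cor Target Pearson correlation of planted pairs, in
#'   (-1, 1\].
#' @param latent_sd Log2-scale SD of the per-sample latent channel driving
#'   planted pairs (default 3.5; must dominate counting noise for the target
#'   correlation to be observable).
#' @param library_size_range Range of per-sample target library sizes.
#' @param genome_lengths Named numeric vector of chromosome lengths (bp).
#' @param read_length Simulated alignment length in bp.
#' @param region_fractions Named fractions (exonic, intronic, intergenic,
#'   splicing) for [simulate_alignments()]; defaults to the control-sample
#'   region profile of the study (78.73 / 16.27 / 4.73 / 0.27%).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mrna = 300L,
                       n_lncrna_known = 150L,
                       n_lncrna_novel = 50L,
                       samples_per_group = 3L,
                       mean_log_expression = 6,
                       sd_log_expression = 1.2,
                       nb_dispersion = 0.05,
                       de_fraction = 0.2,
                       de_log2fc_range = c(2, 4),
                       n_planted_pairs = 10L,
                       planted_cor = 0.99,
                       latent_sd = 3.5,
                       library_size_range = c(8e5, 1.2e6),
                       genome_lengths = c(chr1 = 3e6, chr2 = 3e6,
                                          chr3 = 3e6, chr4 = 3e6),
                       read_length = 50L,
                       region_fractions = c(exonic = 0.7873,
                                            intronic = 0.1627,
                                            intergenic = 0.0473,
                                            splicing = 0.0027)) {
  cfg <- list(seed = as.integer(seed), n_mrna = as.integer(n_mrna),
              n_lncrna_known = as.integer(n_lncrna_known),
              n_lncrna_novel = as.integer(n_lncrna_novel),
              samples_per_group = as.integer(samples_per_group),
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              nb_dispersion = nb_dispersion,
              de_fraction = de_fraction,
              de_log2fc_range = de_log2fc_range,
              n_planted_pairs = as.integer(n_planted_pairs),
              planted_cor = planted_cor,
              latent_sd = latent_sd,
              library_size_range = library_size_range,
              genome_lengths = genome_lengths,
              read_length = as.integer(read_length),
              region_fractions = region_fractions)
  if (cfg$nb_dispersion <= 0) stop_domain("nb_dispersion must be > 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop_domain("de_fraction must be in [0, 1]")
  }
  if (cfg$planted_cor <= -1 || cfg$planted_cor > 1) {
    stop_domain("planted_cor must be in (-1, 1]")
  }
  n_lnc <- cfg$n_lncrna_known + cfg$n_lncrna_novel
  if (cfg$n_planted_pairs > min(cfg$n_mrna, n_lnc)) {
    stop_domain("n_planted_pairs exceeds min(n_mrna, n_lncrna)")
  }
  if (length(cfg$genome_lengths) == 0L || is.null(names(cfg$genome_lengths))) {
    stop_domain("genome_lengths must be a non-empty named vector")
  }
  if (abs(sum(cfg$region_fractions) - 1) > 1e-9) {
    stop_domain("region_fractions must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a transcript annotation
#'
#' Places non-overlapping transcripts with 1-4 exons sequentially along the
#' configured chromosomes (1-based, fully-closed coordinates). Novel
#' lncRNAs always have exonic length > 200 bp; coding potential is planted
#' only later, in the sequences. Errors if the catalogue does not fit the
#' genome, naming the offending chromosome.
#'
#' @param config A [sim_config()].
#' @return List: `annotation` (a [transcript_annotation()]) and `truth`
#'   (list with `novel_lncrna_ids`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_total <- config$n_mrna + config$n_lncrna_known + config$n_lncrna_novel
    biotype <- sample(rep(c("mRNA", "known-lncRNA", "novel-lncRNA"),
                          c(config$n_mrna, config$n_lncrna_known,
                            config$n_lncrna_novel)))
    ids <- sprintf("TX%05d", seq_len(n_total))
    ids[biotype == "novel-lncRNA"] <-
      sprintf("TCONS%05d", which(biotype == "novel-lncRNA"))
    chroms <- names(config$genome_lengths)
    chrom_i <- 1L
    cursor <- 1L
    tx_rows <- vector("list", n_total)
    ex_rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      n_ex <- sample(1:4, 1)
      ## novel lncRNAs must end up > 200 bp even with a single exon
      min_w <- if (biotype[i] == "novel-lncRNA") 250L else 150L
      widths <- sample(min_w:800L, n_ex, replace = TRUE)
      introns <- if (n_ex > 1L) sample(200:2000, n_ex - 1L, replace = TRUE)
                 else integer(0)
      span <- sum(widths) + sum(introns)
      gap <- sample(500:5000, 1)
      start <- cursor + gap
      while (start + span - 1L > config$genome_lengths[chrom_i]) {
        chrom_i <- chrom_i + 1L
        if (chrom_i > length(chroms)) {
          stop_domain("transcripts exceed chromosome length on ",
                      chroms[length(chroms)],
                      ": enlarge genome_lengths or reduce transcript counts")
        }
        cursor <- 1L
        start <- cursor + gap
      }
      ex_start <- start + cumsum(c(0L, widths[-n_ex] + introns))
      ex_end <- ex_start + widths - 1L
      tx_rows[[i]] <- data.frame(transcript_id = ids[i],
                                 chrom = chroms[chrom_i],
                                 start = start, end = max(ex_end),
                                 strand = sample(c("+", "-"), 1),
                                 biotype = biotype[i])
      ex_rows[[i]] <- data.frame(transcript_id = ids[i],
                                 start = ex_start, end = ex_end)
      cursor <- max(ex_end)
    }
    ann <- transcript_annotation(do.call(rbind, tx_rows),
                                 do.call(rbind, ex_rows))
    list(annotation = ann,
         truth = list(novel_lncrna_ids = ids[biotype == "novel-lncRNA"]))
  })
}

#' Simulate transcript sequences
#'
#' Per-transcript random nucleotide sequences of the exonic length with a
#' transcript-specific GC level. mRNAs carry a planted long ORF (~60% of
#' the transcript, >= 300 nt where possible); lncRNA sequences are scrubbed
#' of any ORF reaching `max_orf_aa` amino acids by replacing an in-frame
#' codon with a stop.
#'
#' @param annotation A [transcript_annotation()].
#' @param config A [sim_config()].
#' @param max_orf_aa ORF ceiling enforced on lncRNA sequences (default 100).
#' @return Named `DNAStringSet`.
#' @export
simulate_sequences <- function(annotation, config, max_orf_aa = 100) {
  stopifnot(inherits(config, "sim_config"))
  tx <- annotation$transcripts
  with_seed(config$seed + 1L, {
    seqs <- character(nrow(tx))
    non_stop <- setdiff(c(outer(c(outer(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"), paste0)),
                                c("A", "C", "G", "T"), paste0)),
                        STOP_CODONS)
    for (i in seq_len(nrow(tx))) {
      len <- tx$length[i]
      gc <- runif(1, 0.35, 0.55)
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      s <- paste(sample(names(p), len, replace = TRUE, prob = p),
                 collapse = "")
      if (tx$biotype[i] == "mRNA") {
        orf_nt <- max(300L, 3L * ((len * 6L %/% 10L) %/% 3L))
        orf_nt <- min(orf_nt, 3L * ((len - 3L) %/% 3L))
        if (orf_nt >= 9L) {
          n_codons <- orf_nt %/% 3L - 2L
          orf <- paste0("ATG",
                        paste(sample(non_stop, n_codons, replace = TRUE),
                              collapse = ""),
                        "TAA")
          pos <- sample.int(len - nchar(orf) + 1L, 1)
          substr(s, pos, pos + nchar(orf) - 1L) <- orf
        }
      } else {
        ## scrub coding potential: break any ORF >= max_orf_aa
        repeat {
          orf <- longest_orf(s)
          if (orf$aa < max_orf_aa) break
          hit <- find_orf_position(s, orf$nt)
          mid <- hit$start + 3L * (orf$nt %/% 6L)
          substr(s, mid, mid + 2L) <- "TAA"
        }
      }
      seqs[i] <- s
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- tx$transcript_id
    out
  })
}

## Locate one ORF of the given nt length (start of its ATG, 1-based).
find_orf_position <- function(s, nt) {
  n <- nchar(s)
  for (off in 0:2) {
    len <- (n - off) %/% 3
    if (len < 2L) next
    codons <- substring(s, off + seq(1, by = 3, length.out = len),
                        off + seq(3, by = 3, length.out = len))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% STOP_CODONS)
    for (st in starts) {
      nx <- stops[stops > st]
      if (length(nx) && (nx[1] - st + 1L) * 3L == nt) {
        return(list(start = off + (st - 1L) * 3L + 1L, frame = off))
      }
    }
  }
  stop_domain("internal: ORF of length ", nt, " not found")
}

#' Simulate a count matrix with planted effects
#'
#' Counts are Gamma-Poisson (negative binomial) around per-transcript,
#' per-sample means `mu = baseline * 2^(DE shift + latent channel) * size
#' factor`. Planted DE transcripts have a group-B mean shifted by
#' `2^log2fc`; planted lncRNA-mRNA pairs share a per-sample latent factor
#' (log2 scale) constructed so that the realized sample correlation of the
#' two latent vectors equals `planted_cor` exactly (negative targets give
#' anti-correlated pairs); the observed expression correlation is then the
#' planted value attenuated only by counting noise. The declared library
#' sizes are the simulated total-mapped-read depths (of which the
#' catalogue counts are ~85%), so they may exceed the column sums.
#'
#' @param annotation A [transcript_annotation()] (from
#'   [simulate_annotation()]).
#' @param config A [sim_config()].
#' @param noiseless_pairs If `TRUE` (requires `|planted_cor| = 1`), planted
#'   pair rows are emitted as exact (unrounded) means with no counting
#'   noise, so their empirical correlation is exactly +/-1 — a degenerate
#'   limit used for verification.
#' @return List: `counts` (a [count_matrix()]) and `truth` (list with
#'   `de_transcripts` data.frame (`transcript_id`, `log2fc`) and
#'   `planted_pairs` data.frame (`lncrna_id`, `mrna_id`, `target_cor`)).
#' @export
simulate_counts <- function(annotation, config, noiseless_pairs = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotation$transcripts) == 0L) stop_domain("empty annotation")
  if (config$samples_per_group < 2L) {
    stop_domain("samples_per_group must be >= 2")
  }
  if (noiseless_pairs && abs(config$planted_cor) != 1) {
    stop_domain("noiseless_pairs requires |planted_cor| = 1")
  }
  tx <- annotation$transcripts
  nt <- nrow(tx)
  ns <- 2L * config$samples_per_group
  group <- rep(c("control", "SAH"), each = config$samples_per_group)
  sample_ids <- paste0(rep(c("ctrl", "sah"), each = config$samples_per_group),
                       seq_len(config$samples_per_group))
  with_seed(config$seed + 2L, {
    base_log2 <- rnorm(nt, config$mean_log_expression,
                       config$sd_log_expression)

    ## planted pairs: lncRNA and mRNA ids, boosted baseline so the latent
    ## channel dominates counting noise. The two latent vectors are built
    ## by Gram-Schmidt so their REALIZED sample correlation equals the
    ## target exactly; with n = 6 samples, planting only in expectation
    ## would let the sampling variability of r (Fisher-z sd ~ 1/sqrt(n-3))
    ## swamp the planted value.
    lnc_ids <- tx$transcript_id[tx$biotype != "mRNA"]
    mrna_ids <- tx$transcript_id[tx$biotype == "mRNA"]
    np <- config$n_planted_pairs
    pairs <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                        target_cor = numeric(0))
    lat <- matrix(0, nt, ns)  # log2-scale latent contribution
    if (np > 0) {
      pl <- sample(lnc_ids, np)
      pm <- sample(mrna_ids, np)
      pairs <- data.frame(lncrna_id = pl, mrna_id = pm,
                          target_cor = config$planted_cor)
      rho <- config$planted_cor
      for (k in seq_len(np)) {
        il <- match(pl[k], tx$transcript_id)
        im <- match(pm[k], tx$transcript_id)
        base_log2[c(il, im)] <- pmax(base_log2[c(il, im)], 9)
        f <- rnorm(ns)
        u <- (f - mean(f)) / sd(f)
        w <- rnorm(ns)
        w <- w - mean(w)
        w <- w - u * sum(u * w) / sum(u * u)   # orthogonal to u, centered
        w <- if (sd(w) > 0) w / sd(w) else w
        v <- rho * u + sqrt(1 - rho^2) * w     # cor(u, v) == rho exactly
        lat[il, ] <- config$latent_sd * u
        lat[im, ] <- config$latent_sd * v
      }
    }

    ## planted DE, disjoint from pair members: a transcript carrying both a
    ## fold-change shift and the dominant latent channel would have an
    ## ambiguous ground-truth label (the latent swamps the shift at n = 6)
    pool <- setdiff(seq_len(nt),
                    match(c(pairs$lncrna_id, pairs$mrna_id),
                          tx$transcript_id))
    n_de <- min(round(config$de_fraction * nt), length(pool))
    de_idx <- if (n_de > 0) sample(pool, n_de) else integer(0)
    lfc <- numeric(nt)
    if (n_de > 0) {
      lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        runif(n_de, config$de_log2fc_range[1], config$de_log2fc_range[2])
    }

    ## per-sample size factors towards target sequencing depths. The
    ## factor uses the EXPECTED catalogue total (constant across samples),
    ## and the declared library size is the total-mapped-read count
    ## (catalogue counts are ~85% of it): normalizing by the realized
    ## column sum instead would inject a compositional common mode into
    ## RPKM and correlate otherwise independent transcripts.
    target <- runif(ns, config$library_size_range[1],
                    config$library_size_range[2])
    de_shift <- outer(lfc, as.numeric(group == "SAH"))
    mu_rel <- 2^(base_log2 + de_shift + lat)
    sf <- target / mean(colSums(mu_rel))
    mu <- sweep(mu_rel, 2, sf, "*")

    size <- 1 / config$nb_dispersion
    counts <- matrix(
      if (config$nb_dispersion < 1e-8) rpois(nt * ns, lambda = mu)
      else rnbinom(nt * ns, mu = mu, size = size),
      nt, ns)
    if (noiseless_pairs && np > 0) {
      pr <- match(c(pairs$lncrna_id, pairs$mrna_id), tx$transcript_id)
      counts[pr, ] <- mu[pr, ]
    }
    rownames(counts) <- tx$transcript_id
    colnames(counts) <- sample_ids
    cm <- count_matrix(counts, library_sizes = round(target / 0.85),
                       group = group)
    list(counts = cm,
         truth = list(de_transcripts = data.frame(
                        transcript_id = tx$transcript_id[de_idx],
                        log2fc = lfc[de_idx]),
                      planted_pairs = pairs))
  })
}

#' Simulate read alignments with known region labels
#'
#' Emits `n_reads` aligned intervals apportioned exactly (largest
#' remainder) to the configured exonic / intronic / intergenic / splicing
#' fractions. Exonic reads lie inside single exons, intronic reads inside
#' introns, intergenic reads in transcript-free gaps, and splicing reads
#' span an exon-exon junction as two blocks. The ground-truth label is
#' carried in the `region_truth` column.
#'
#' @param annotation A [transcript_annotation()].
#' @param config A [sim_config()] (read length and region fractions).
#' @param n_reads Number of reads (default 20000; 0 yields an empty set).
#' @return A `read_alignments` data.frame.
#' @export
simulate_alignments <- function(annotation, config, n_reads = 20000L) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotation$transcripts) == 0L) stop_domain("empty annotation")
  fr <- config$region_fractions
  if (abs(sum(fr) - 1) > 1e-9) stop_domain("region_fractions must sum to 1")
  empty <- data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), block_sizes = character(0),
                      block_starts = character(0),
                      region_truth = character(0))
  class(empty) <- c("read_alignments", "data.frame")
  if (n_reads == 0L) return(empty)
  rl <- config$read_length

  with_seed(config$seed + 3L, {
    n_per <- apportion(n_reads, fr[c("exonic", "intronic", "intergenic",
                                     "splicing")])
    names(n_per) <- c("exonic", "intronic", "intergenic", "splicing")
    tx <- annotation$transcripts

    ex <- exon_granges(annotation)
    intr <- intron_granges(annotation)
    ## intergenic gaps: complement of transcript spans within chromosomes
    txg <- GenomicRanges::reduce(tx_granges(annotation), ignore.strand = TRUE)
    sl <- config$genome_lengths
    gap_df <- do.call(rbind, lapply(names(sl), function(ch) {
      covered <- IRanges::ranges(txg[GenomicRanges::seqnames(txg) == ch])
      g <- IRanges::gaps(covered, start = 1L, end = as.integer(sl[[ch]]))
      if (length(g) == 0L) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(g), end = IRanges::end(g))
    }))
    gaps <- GenomicRanges::GRanges(gap_df$chrom,
                                   IRanges::IRanges(gap_df$start, gap_df$end))

    place_in <- function(pool, n, label) {
      if (n == 0L) return(NULL)
      pool <- pool[GenomicRanges::width(pool) >= rl]
      if (length(pool) == 0L) {
        stop_domain("no ", label, " region can host a ", rl, " bp read")
      }
      pick <- sample.int(length(pool), n, replace = TRUE)
      w <- GenomicRanges::width(pool)[pick]
      off <- floor(runif(n) * (w - rl + 1))
      st <- GenomicRanges::start(pool)[pick] + as.integer(off)
      data.frame(chrom = as.character(GenomicRanges::seqnames(pool)[pick]),
                 start = st, end = st + rl - 1L,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 block_sizes = as.character(rl),
                 block_starts = as.character(st),
                 region_truth = label)
    }

    rows <- list(place_in(ex, n_per[["exonic"]], "exonic"),
                 place_in(intr, n_per[["intronic"]], "intronic"),
                 place_in(gaps, n_per[["intergenic"]], "intergenic"))

    if (n_per[["splicing"]] > 0L) {
      ## junction table from multi-exon transcripts
      sp <- split(annotation$exons, annotation$exons$transcript_id)
      jxn <- do.call(rbind, lapply(sp, function(e) {
        if (nrow(e) < 2L) return(NULL)
        data.frame(transcript_id = e$transcript_id[1],
                   left_end = e$end[-nrow(e)], right_start = e$start[-1],
                   left_start = e$start[-nrow(e)], right_end = e$end[-1])
      }))
      if (is.null(jxn) || nrow(jxn) == 0L) {
        stop_domain("no splicing junction available for splicing reads")
      }
      n <- n_per[["splicing"]]
      j <- jxn[sample.int(nrow(jxn), n, replace = TRUE), ]
      m <- pmin(pmax(sample.int(rl - 10L, n, replace = TRUE) + 5L, 6L),
                rl - 6L)
      m <- pmin(m, j$left_end - j$left_start + 1L)
      m2 <- pmin(rl - m, j$right_end - j$right_start + 1L)
      b1s <- j$left_end - m + 1L
      b2s <- j$right_start
      chrom <- tx$chrom[match(j$transcript_id, tx$transcript_id)]
      rows <- c(rows, list(data.frame(
        chrom = chrom, start = b1s, end = b2s + m2 - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        block_sizes = paste(m, m2, sep = ","),
        block_starts = paste(b1s, b2s, sep = ","),
        region_truth = "splicing")))
    }

    out <- do.call(rbind, rows)
    out <- data.frame(name = sprintf("read%06d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    class(out) <- c("read_alignments", "data.frame")
    out
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the annotation (GTF), counts and sample table (TSV), alignments
#' (BED), sequences (FASTA), a toy gene-set collection (GMT, random
#' groupings of mRNA ids for exercising enrichment), the ground truth
#' (JSON) and a manifest listing relative paths with MD5 checksums.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created; must be writable).
#' @param n_reads Alignment count passed to [simulate_alignments()].
#' @return The manifest as a list (invisibly written to `manifest.json`).
#' @export
write_fixture <- function(config, out_dir, n_reads = 20000L) {
  stopifnot(inherits(config, "sim_config"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_domain("cannot create out_dir: ", out_dir)
  sim <- simulate_annotation(config)
  seqs <- simulate_sequences(sim$annotation, config)
  cnt <- simulate_counts(sim$annotation, config)
  aln <- simulate_alignments(sim$annotation, config, n_reads = n_reads)

  files <- c(annotation = "annotation.gtf", counts = "counts.tsv",
             samples = "counts_samples.tsv", alignments = "alignments.bed",
             sequences = "sequences.fa", genesets = "genesets.gmt",
             truth = "truth.json")
  write_gtf(sim$annotation, file.path(out_dir, files["annotation"]))
  write_counts_tsv(cnt$counts, file.path(out_dir, files["counts"]),
                   file.path(out_dir, files["samples"]))
  write_bed(aln, file.path(out_dir, files["alignments"]))
  write_fasta(seqs, file.path(out_dir, files["sequences"]))

  mrna_ids <- sim$annotation$transcripts$transcript_id[
    sim$annotation$transcripts$biotype == "mRNA"]
  sets <- with_seed(config$seed + 4L, {
    ns <- max(3L, min(10L, length(mrna_ids) %/% 20L))
    stats::setNames(
      lapply(seq_len(ns), function(i) {
        sort(sample(mrna_ids, min(length(mrna_ids),
                                  sample(10:30, 1))))
      }),
      sprintf("SET%02d", seq_len(ns)))
  })
  write_gmt(sets, file.path(out_dir, files["genesets"]))

  truth <- list(novel_lncrna_ids = sim$truth$novel_lncrna_ids,
                de_transcripts = cnt$truth$de_transcripts,
                planted_pairs = cnt$truth$planted_pairs)
  jsonlite::write_json(truth, file.path(out_dir, files["truth"]),
                       dataframe = "columns", auto_unbox = FALSE,
                       digits = NA)

  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config = unclass(config),
                   files = lapply(seq_along(files), function(i) {
                     list(role = names(files)[i],
                          path = unname(files[i]),
                          md5 = unname(sums[i]))
                   }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
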