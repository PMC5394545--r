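## End-to-end orchestration: expression -> differential expression ->
## lncRNA classification -> co-expression network -> enrichment, driven by
## one flat JSON config, with a JSON manifest recording every stage's
## parameters and output checksums. Reruns with the same config reproduce
## identical non-log outputs.

default_pipeline_config <- function() {
  list(annotation = NULL, counts = NULL, samples = NULL, sequences = NULL,
       genesets = NULL,
       out_dir = NULL,
       gc_normalize = FALSE, gc_bins = 10,
       log2fc = 1, alpha = 0.05,
       heatmap_log2fc = 1.5, heatmap_alpha = 0.05,
       cor_threshold = 0.95, cor_alpha = 0.05,
       min_length = 200, max_orf_aa = 100, window_bp = 100000,
       perm_mode = "auto", n_perm = 10000, seed = 1L,
       q_method = "BH")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: `expression` (optional GC normalization, RPKM,
#' log10(RPKM+1)), `diffexpr` (conditional binomial test, q-values,
#' significance filter), `lncrna_id` (match against the known catalogue,
#' classify novel lncRNAs), `coexpression` (bipartite permutation-test
#' network on significant transcripts), `enrichment` (hypergeometric
#' over-representation of significant mRNAs; skipped without gene sets).
#' Stage failures halt the run naming the stage; outputs written so far are
#' retained.
#'
#' @param config Named list overriding the defaults: input paths
#'   (`annotation`, `counts`, `samples`, `sequences`, `genesets`),
#'   `out_dir`, thresholds (`log2fc`, `alpha`, `cor_threshold`,
#'   `cor_alpha`, `min_length`, `max_orf_aa`, `window_bp`,
#'   `heatmap_log2fc`, `heatmap_alpha`), normalization toggles
#'   (`gc_normalize`, `gc_bins`), permutation settings (`perm_mode`,
#'   `n_perm`, `seed`) and `q_method`. Unknown keys are rejected.
#' @return The run manifest (list), also written to
#'   `<out_dir>/run_manifest.json`.
#' @export
run_pipeline <- function(config) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_domain("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  for (key in c("annotation", "counts", "out_dir")) {
    if (is.null(cfg[[key]])) stop_domain("config requires '", key, "'")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t0 <- Sys.time()
  log_msg <- function(stage, ...) {
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
  }
  run_stage <- function(name, fun) {
    log_msg(name, "start")
    out <- tryCatch(fun(), error = function(e) {
      stop_domain("stage '", name, "' failed: ", conditionMessage(e))
    })
    stages[[name]] <<- out
    log_msg(name, "done")
    out
  }
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  ann <- read_gtf(cfg$annotation)
  cm <- read_counts_tsv(cfg$counts,
                        cfg$samples %||% sub("\\.tsv$", "_samples.tsv",
                                             cfg$counts))
  seqs <- if (!is.null(cfg$sequences)) read_fasta(cfg$sequences) else NULL
  lengths <- setNames(ann$transcripts$length, ann$transcripts$transcript_id)
  biotypes <- setNames(ann$transcripts$biotype, ann$transcripts$transcript_id)

  ## -- expression ----------------------------------------------------
  expr <- run_stage("expression", function() {
    cm2 <- cm
    if (isTRUE(cfg$gc_normalize)) {
      if (is.null(seqs)) stop("gc_normalize requires sequences")
      gc <- gc_distribution(seqs)$gc
      cm2 <- gc_normalize(cm2, gc, n_bins = cfg$gc_bins)
    }
    e <- log_transform(rpkm(cm2, lengths))
    path <- emit(file.path(cfg$out_dir, "expression_log10_rpkm.tsv"))
    write.table(data.frame(transcript_id = rownames(e$values), e$values,
                           check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(expr = e, cm = cm2,
         params = cfg[c("gc_normalize", "gc_bins")], outputs = path)
  })

  ## -- diffexpr ------------------------------------------------------
  de <- run_stage("diffexpr", function() {
    det <- run_de(expr$cm, biotypes = biotypes, q_method = cfg$q_method)
    flt <- significance_filter(det, cfg$log2fc, cfg$alpha)
    path <- emit(file.path(cfg$out_dir, "differential_expression.tsv"))
    out <- flt$records
    out$fold_change <- round(out$fold_change, 6)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(records = flt$records, summary = flt$summary,
         params = cfg[c("log2fc", "alpha", "q_method")], outputs = path)
  })

  ## -- lncrna_id -----------------------------------------------------
  lnc <- run_stage("lncrna_id", function() {
    known <- ann$transcripts$biotype %in% c("mRNA", "known-lncRNA")
    reference <- transcript_annotation(
      ann$transcripts[known, , drop = FALSE],
      ann$exons[ann$exons$transcript_id %in%
                  ann$transcripts$transcript_id[known], , drop = FALSE])
    status <- match_known(ann, reference)
    cls <- if (is.null(seqs)) {
      warning("no sequences: novel lncRNA classification skipped",
              call. = FALSE)
      NULL
    } else {
      classify_novel_lncrna(ann, seqs, status,
                            min_length = cfg$min_length,
                            max_orf_aa = cfg$max_orf_aa)
    }
    path <- emit(file.path(cfg$out_dir, "lncrna_classification.tsv"))
    if (!is.null(cls)) {
      write.table(cls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      writeLines(paste("transcript_id", "length", "matched", "orf_aa",
                       "class", sep = "\t"), path)
    }
    list(match_status = status, classification = cls,
         params = cfg[c("min_length", "max_orf_aa")], outputs = path)
  })

  ## -- coexpression --------------------------------------------------
  coexp <- run_stage("coexpression", function() {
    vals <- expr$expr$values
    is_lnc <- biotypes[rownames(vals)] %in% c("known-lncRNA", "novel-lncRNA")
    net <- build_network(vals[is_lnc, , drop = FALSE],
                         vals[biotypes[rownames(vals)] == "mRNA", ,
                              drop = FALSE],
                         cor_threshold = cfg$cor_threshold,
                         alpha = cfg$cor_alpha,
                         de_records = de$records,
                         mode = cfg$perm_mode, n_perm = cfg$n_perm,
                         seed = cfg$seed)
    paths <- export_network(net, cfg$out_dir, format = "sif",
                            prefix = "coexpression")
    for (p in paths) emit(p)
    list(network = net,
         params = cfg[c("cor_threshold", "cor_alpha", "perm_mode",
                        "n_perm", "seed")],
         outputs = paths)
  })

  ## -- enrichment ----------------------------------------------------
  run_stage("enrichment", function() {
    if (is.null(cfg$genesets)) {
      return(list(status = "skipped (no gene sets)", outputs = character(0)))
    }
    sets <- read_gmt(cfg$genesets)
    rec <- de$records
    sig_mrna <- rec$transcript_id[rec$significant &
                                    rec$biotype %in% "mRNA"]
    universe <- rec$transcript_id[rec$biotype %in% "mRNA"]
    if (length(sig_mrna) == 0L) {
      return(list(status = "skipped (no significant mRNAs)",
                  outputs = character(0)))
    }
    enr <- hypergeom_enrich(sig_mrna, sets, universe)
    path <- emit(file.path(cfg$out_dir, "enrichment.tsv"))
    write.table(enr, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(records = enr, params = list(), outputs = path)
  })

  manifest <- list(
    config = cfg,
    stages = lapply(names(stages), function(nm) {
      st <- stages[[nm]]
      outs <- st$outputs %||% character(0)
      list(name = nm,
           params = st$params %||% list(),
           status = st$status %||% "ok",
           outputs = lapply(outs, function(p) {
             list(path = basename(p), md5 = unname(tools::md5sum(p)))
           }))
    }),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Minimal command-line entry point
#'
#' Subcommands: `simulate --seed S --out DIR [--config cfg.json]` writes a
#' synthetic fixture; `run --config cfg.json` runs the pipeline. Config
#' files are flat JSON documents whose keys mirror [sim_config()] /
#' [run_pipeline()] arguments. Returns (and, under `Rscript`, exits with)
#' 0 on success, 2 on usage/validation errors, 1 on runtime failure.
#'
#' @param args Character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly.
#' @export
sahnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: sahnet simulate --seed S --out DIR [--config cfg.json]\n",
            "       sahnet run --config cfg.json")
    invisible(2L)
  }
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  if (length(args) == 0L) return(usage())
  cmd <- args[1]
  code <- tryCatch({
    if (cmd == "simulate") {
      out <- get_opt("--out")
      if (is.null(out)) return(usage())
      extra <- get_opt("--config")
      base <- if (!is.null(extra)) jsonlite::read_json(extra,
                                                       simplifyVector = TRUE)
              else list()
      base$seed <- as.integer(get_opt("--seed", base$seed %||% 1L))
      cfg <- do.call(sim_config, base)
      write_fixture(cfg, out)
      message("fixture written to ", out)
      0L
    } else if (cmd == "run") {
      cfgp <- get_opt("--config")
      if (is.null(cfgp)) return(usage())
      cfg <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
      run_pipeline(cfg)
      0L
    } else usage()
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
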