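#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end workflow (cluster -> featurize ->
#' assemble -> select -> cross-validated evaluation) in one serializable
#' list. A configuration plus fixed inputs determines the run: all
#' randomness derives from `seed`.
#'
#' @param fasta path to transcript FASTA (required unless `dataset` is
#'   passed to [run_pipeline()]).
#' @param exons,conservation,variants,interactions,labels optional paths to
#'   the annotation inputs (BED, bedGraph-like, BED-like, TSV, TSV).
#' @param dotbracket optional RNAfold-style structure file; when absent the
#'   fallback folder is used.
#' @param cluster run redundancy filtering first (default `TRUE`).
#' @param cluster_threshold identity threshold (default 0.6).
#' @param k k-mer sizes (default `c(2, 3)`).
#' @param lam,w pseudo-composition parameters (defaults 10, 0.05).
#' @param max_fold_len fallback-folder truncation cap (default 300).
#' @param models model kinds to evaluate (default all three).
#' @param selection `"per_fold"` (leakage-free default), `"once"`
#'   ("paper mode": select on all data before CV), or `"none"`.
#' @param n_folds CV folds (default 10).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(fasta = NULL, exons = NULL, conservation = NULL,
                            variants = NULL, interactions = NULL,
                            labels = NULL, dotbracket = NULL,
                            cluster = TRUE, cluster_threshold = 0.6,
                            k = c(2, 3), lam = 10, w = 0.05,
                            max_fold_len = 300,
                            models = c("svm", "rf", "elm"),
                            selection = c("per_fold", "once", "none"),
                            n_folds = 10, seed = 1) {
  selection <- match.arg(selection)
  models <- match.arg(models, c("svm", "rf", "elm"), several.ok = TRUE)
  structure(list(fasta = fasta, exons = exons, conservation = conservation,
                 variants = variants, interactions = interactions,
                 labels = labels, dotbracket = dotbracket,
                 cluster = cluster, cluster_threshold = cluster_threshold,
                 k = k, lam = lam, w = w, max_fold_len = max_fold_len,
                 models = models, selection = selection,
                 n_folds = n_folds, seed = seed), class = "run_config")
}

#' Run the full prediction pipeline
#'
#' Executes the staged workflow on file inputs described by `config` (or on
#' an in-memory `dataset` from [generate_dataset()]): redundancy filtering,
#' sequence and structure featurization, design-matrix assembly, feature
#' selection, and stratified cross-validated evaluation of every requested
#' model. When `outdir` is given, each artifact is written (features TSV,
#' selection JSON, per-model CV report JSON, retained FASTA, log with seeds
#' and MD5 checksums).
#'
#' @param config a [pipeline_config()].
#' @param dataset optional in-memory dataset (overrides the file inputs).
#' @param outdir optional output directory.
#' @return list of class `lnc_run`: `cluster` (`cluster_report` or `NULL`),
#'   `features` (`feature_matrix`), `selection` (`selection_result` of the
#'   whole-data selection when `selection = "once"`, else `NULL`),
#'   `reports` (named list of `cv_report`s), `config`.
#' @export
run_pipeline <- function(config, dataset = NULL, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load"
  result <- tryCatch({
    if (is.null(dataset)) {
      if (is.null(config$fasta)) stopf("config$fasta or dataset required")
      labels <- NULL
      genes <- NULL
      if (!is.null(config$labels)) {
        lt <- read.table(config$labels, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
        labels <- setNames(lt$label, lt$transcript_id)
        if ("gene_id" %in% names(lt))
          genes <- setNames(lt$gene_id, lt$transcript_id)
      }
      records <- read_fasta(config$fasta, labels = labels)
      bed <- if (!is.null(config$exons)) read_bed_intervals(config$exons)
             else NULL
      for (id in names(records)) {
        gid <- if (!is.null(genes) && id %in% names(genes)) genes[[id]]
               else records[[id]]$gene_id
        ex <- if (!is.null(bed))
          bed[bed$name == id, c("chrom", "start", "end", "strand")]
        else NULL
        if (!is.null(ex) && nrow(ex) == 0) ex <- NULL
        if (!identical(gid, records[[id]]$gene_id) || !is.null(ex))
          records[[id]] <- transcript_record(
            id, records[[id]]$sequence, gene_id = gid,
            exons = ex, label = records[[id]]$label)
      }
      track <- if (!is.null(config$conservation))
        read_conservation(config$conservation) else NULL
      variants <- if (!is.null(config$variants))
        read_variants(config$variants) else NULL
      interactions <- if (!is.null(config$interactions))
        read_interactions(config$interactions) else NULL
      structures <- if (!is.null(config$dotbracket))
        read_dotbracket(config$dotbracket) else NULL
    } else {
      records <- dataset$records
      track <- dataset$track
      variants <- dataset$variants
      interactions <- dataset$interactions
      structures <- dataset$structures
    }

    stage <- "cluster"
    cl <- NULL
    if (isTRUE(config$cluster)) {
      cl <- greedy_cluster(records, threshold = config$cluster_threshold)
      records <- retained_records(records, cl)
    }

    stage <- "featurize"
    seq_f <- featurize_sequences(records, track = track,
                                 variants = variants,
                                 interactions = interactions,
                                 k = config$k, lam = config$lam,
                                 w = config$w)
    struct_f <- featurize_structures(records, structures = structures,
                                     max_fold_len = config$max_fold_len)

    stage <- "assemble"
    labs <- vapply(records, `[[`, "", "label")
    fm <- assemble_features(seq_f, struct_f,
                            labels = if (all(labs == "unknown")) NULL
                                     else labs)

    stage <- "select"
    sel <- NULL
    if (config$selection == "once" && !is.null(fm$labels))
      sel <- select_features(fm, seed = derive_seed(config$seed, 777L))

    stage <- "evaluate"
    reports <- list()
    if (!is.null(fm$labels)) {
      for (kind in config$models) {
        spec <- model_spec(kind, seed = derive_seed(config$seed,
                                                    match(kind, config$models)))
        reports[[kind]] <- evaluate_cv(spec, fm, k = config$n_folds,
                                       selection = config$selection,
                                       seed = config$seed)
      }
    }
    list(cluster = cl, features = fm, selection = sel, reports = reports)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  run <- structure(c(result, list(config = config)), class = "lnc_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.lnc_run <- function(x, ...) {
  cat("<lnc_run>\n")
  if (!is.null(x$cluster))
    cat(sprintf("  clustering: %d -> %d sequences (>= %.0f%% identity removed)\n",
                nrow(x$cluster$assignments),
                length(x$cluster$retained_ids),
                100 * x$cluster$threshold))
  cat(sprintf("  features  : %d transcripts x %d columns\n",
              nrow(x$features$x), ncol(x$features$x)))
  for (kind in names(x$reports)) {
    a <- x$reports[[kind]]$aggregate
    cat(sprintf("  %-3s CV    : F1 %.3f  precision %.3f  recall %.3f  AUC %.3f (min %.2f, max %.2f)\n",
                kind, a["mean", "f1"], a["mean", "precision"],
                a["mean", "recall"], a["mean", "auc"],
                a["min", "auc"], a["max", "auc"]))
  }
  invisible(x)
}

# serialize a run: features TSV, selection + reports JSON, log with
# checksums; everything plain text
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fpath <- file.path(outdir, "features.tsv")
  df <- data.frame(transcript_id = rownames(run$features$x),
                   run$features$x, check.names = FALSE)
  if (!is.null(run$features$labels)) df$label <- run$features$labels
  write.table(df, fpath, sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- fpath
  if (!is.null(run$selection)) {
    spath <- file.path(outdir, "selection.json")
    jsonlite::write_json(list(kept = run$selection$kept,
                              threshold = run$selection$threshold,
                              seed = run$selection$seed,
                              importances = as.list(run$selection$importances)),
                         spath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, spath)
  }
  for (kind in names(run$reports)) {
    rpath <- file.path(outdir, sprintf("cv_report_%s.json", kind))
    rep <- run$reports[[kind]]
    jsonlite::write_json(list(model = kind,
                              per_fold = rep$per_fold,
                              aggregate = as.data.frame(rep$aggregate),
                              selection = rep$selection,
                              seed = rep$seed),
                         rpath, auto_unbox = TRUE, digits = NA, na = "null")
    paths <- c(paths, rpath)
  }
  if (!is.null(run$cluster)) {
    cpath <- file.path(outdir, "clusters.tsv")
    write.table(run$cluster$assignments, cpath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, cpath)
  }
  log <- c(sprintf("lncdisc run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           sprintf("seed: %d", run$config$seed),
           sprintf("R version: %s", R.version.string),
           sprintf("selection mode: %s", run$config$selection),
           "artifact checksums (md5):",
           sprintf("  %s  %s", tools::md5sum(paths), basename(paths)))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(outdir)
}
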