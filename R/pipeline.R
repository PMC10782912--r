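# One-config orchestration of the stage functions, with a run manifest.
#
# The config is JSON (one `seed` field derives every stage seed). Stages
# run in the fixed order windows -> count -> correct -> matrix -> impute ->
# train -> evaluate -> rank -> annotate -> enrich; stages whose inputs are
# supplied precomputed (or whose optional inputs are absent) are skipped
# and recorded as such in the manifest.

pipeline_stages <- c("windows", "count", "correct", "matrix", "impute",
                     "train", "evaluate", "rank", "annotate", "enrich")

require_field <- function(config, field) {
  if (is.null(config[[field]]))
    stop2("config missing required field: ", field)
  config[[field]]
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(character(0))
  as.vector(tools::md5sum(paths))
}

#' Run the full screening pipeline from one config
#'
#' The JSON config declares inputs and parameters; see the package vignette
#' for the schema. Three input modes are supported: `simulate` (generate a
#' synthetic cohort in place), `samples` (per-sample bedGraph depth files
#' plus `chrom_sizes`/`window_size`), or `matrix` (a precomputed coverage
#' matrix TSV from [write_matrix()], skipping the window/count stages).
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return A `run_manifest`: tool version, config hash, master seed, and
#'   per-stage status with output file digests and timestamps.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config_hash <- NA_character_
  if (is.character(config) && length(config) == 1L) {
    config_hash <- as.vector(tools::md5sum(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop2("config must be a path or a named list")
  out_dir <- out_dir %||% config$out_dir %||% stop2(
    "config missing required field: out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  manifest <- list(
    tool = "cfcnv", version = as.character(utils::packageVersion("cfcnv")),
    config_hash = config_hash, seed = seed, started = format(Sys.time()),
    stages = list())
  note <- function(stage, status, outputs = character(0)) {
    manifest$stages[[stage]] <<- list(
      status = status, outputs = as.list(outputs),
      digests = as.list(file_digest(outputs)),
      timestamp = format(Sys.time()))
  }
  truth <- NULL
  ws <- NULL

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% derive_seed(seed, "simulate")
    if (!is.null(sim_args$chrom_lengths))
      sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
    scfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(scfg)
    ws <- cohort$ws
    truth <- cohort$truth
    cm <- cohort_matrix(cohort)
    labels <- cohort$labels
    note("windows", "executed (simulated)")
    note("count", "executed (simulated)")
    note("correct", "skipped (simulated counts)")
  } else if (!is.null(config$matrix)) {
    cm <- read_matrix(config$matrix)
    labels <- cm$labels
    if (!is.null(config$chrom_sizes)) {
      ws <- make_windows(load_chrom_sizes(config$chrom_sizes),
                         require_field(config, "window_size"))
    }
    note("windows", if (is.null(ws)) "skipped (precomputed matrix)"
         else "executed")
    note("count", "skipped (precomputed matrix)")
    note("correct", "skipped (precomputed matrix)")
  } else {
    cs <- load_chrom_sizes(require_field(config, "chrom_sizes"))
    ws <- make_windows(cs, require_field(config, "window_size"))
    if (!is.null(config$exclude))
      ws <- mask_windows(ws, config$exclude,
                         config$min_overlap_fraction %||% 0.5)
    if (!is.null(config$gc) || !is.null(config$mappability))
      ws <- annotate_windows(ws, gc = config$gc,
                             mappability = config$mappability)
    wbed <- file.path(out_dir, "windows.bed")
    write_windows_bed(ws, wbed)
    note("windows", "executed", wbed)
    samples <- require_field(config, "samples")
    labels_df <- utils::read.delim(require_field(config, "labels"))
    if (is.data.frame(samples)) samples <- split(samples, seq_len(nrow(samples)))
    profiles <- lapply(samples, function(s) {
      p <- count_coverage(ws, s$depth, sample_id = s$id,
                          n_unique_reads = s$n_unique_reads %||% NA_integer_)
      suppressWarnings(sample_qc(
        p, min_mean_depth = config$min_mean_depth %||% 0.15,
        min_reads = config$min_reads %||% 6e6))
    })
    note("count", "executed")
    if (isTRUE(config$correct) && !is.null(ws$gc)) {
      profiles <- lapply(profiles, function(p)
        if (isFALSE(p$qc_pass)) p else correct_bias(p, ws))
      note("correct", "executed")
    } else note("correct", "skipped (no GC track or disabled)")
    labels <- stats::setNames(labels_df$label, labels_df$sample_id)
    cm <- assemble_matrix(profiles, labels)
    labels <- cm$labels
  }

  cm <- normalize_rows(cm)
  pr_cfg <- config$prune %||% list()
  pruned <- prune_windows(cm,
                          dropout_frac = pr_cfg$dropout_frac %||% 0.8,
                          dropout_value = pr_cfg$dropout_value %||% 0.1,
                          mean_diff = pr_cfg$mean_diff %||% 0.01)
  cm <- pruned$matrix
  mpath <- file.path(out_dir, "matrix.tsv")
  write_matrix(cm, mpath, report = pruned$report)
  note("matrix", "executed", c(mpath, paste0(mpath, ".json")))

  im_cfg <- config$impute %||% list()
  mask <- flag_missing(cm, epsilon = im_cfg$epsilon %||% 0.01)
  cm <- impute_lowrank(cm, mask,
                       rank = im_cfg$rank %||% 10,
                       lambda = im_cfg$lambda %||% 0.1,
                       lr = im_cfg$lr %||% 0.05,
                       epochs = im_cfg$epochs %||% 500,
                       seed = derive_seed(seed, "impute"))
  ipath <- file.path(out_dir, "imputed.tsv")
  write_matrix(cm, ipath)
  loss_path <- file.path(out_dir, "impute_loss.tsv")
  write_tsv(data.frame(epoch = seq_along(attr(cm, "loss")),
                       loss = attr(cm, "loss")), loss_path)
  note("impute", "executed", c(ipath, loss_path))

  mdl_args <- config$model %||% list()
  mdl_args$seed <- mdl_args$seed %||% derive_seed(seed, "model")
  mcfg <- do.call(model_config, mdl_args)
  sp <- split_dataset(nrow(cm$values), seed = derive_seed(seed, "split"))
  X <- cm$values
  mdl <- build_model(mcfg, ncol(X))
  mdl <- train_model(mdl, X[sp$train, , drop = FALSE], labels[sp$train],
                     X[sp$val, , drop = FALSE], labels[sp$val])
  hpath <- file.path(out_dir, "history.tsv")
  write_tsv(mdl$history, hpath)
  note("train", "executed", hpath)

  p_test <- predict(mdl, X[sp$test, , drop = FALSE])
  report <- evaluate_predictions(labels[sp$test], p_test, mcfg$threshold)
  boot <- bootstrap_auc(labels[sp$test], p_test,
                        n_reps = config$bootstrap %||% 1000,
                        seed = derive_seed(seed, "bootstrap"))
  epath <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(list(
    n_test = report$n, accuracy = report$accuracy,
    precision = report$precision, recall = report$recall, f1 = report$f1,
    auc = report$auc, pearson_r = report$pearson_r,
    p_value = report$p_value, bootstrap_mean_auc = boot$mean_auc,
    bootstrap_ci95 = boot$ci95), epath, auto_unbox = TRUE, digits = NA)
  rpath <- file.path(out_dir, "roc.tsv")
  write_tsv(report$roc, rpath)
  note("evaluate", "executed", c(epath, rpath))

  if (!is.null(ws)) {
    w_att <- attention_weights(mdl, X[sp$train, , drop = FALSE])
    full_w <- numeric(nrow(ws$windows))
    full_w[match(cm$window_indices, ws$windows$index)] <- w_att
    rr <- rank_windows(full_w, ws,
                       top_k = min(config$top_k %||% 5000,
                                   nrow(ws$windows)))
    bpath <- file.path(out_dir, "top_windows.bed")
    write_regions_bed(rr, bpath)
    outs <- bpath
    if (!is.null(truth) && nrow(truth) > 0) {
      rec <- truth_recovery(rr, truth,
                            k = min(2L * length(unique(truth$window_index)),
                                    nrow(rr$regions)),
                            n_universe = nrow(ws$windows))
      jsonlite::write_json(rec, file.path(out_dir, "recovery.json"),
                           auto_unbox = TRUE, digits = NA)
      outs <- c(outs, file.path(out_dir, "recovery.json"))
    }
    note("rank", "executed", outs)
    if (!is.null(config$genes)) {
      genes <- annotate_genes(rr, config$genes)
      gpath <- file.path(out_dir, "genes.txt")
      writeLines(genes, gpath)
      note("annotate", "executed", gpath)
      if (!is.null(config$gene_sets)) {
        universe <- if (!is.null(config$universe))
          readLines(config$universe)
        else unique(read_intervals(config$genes,
                                   c("chrom", "start", "end", "name"))$name)
        enr <- ora_enrich(genes, config$gene_sets, universe)
        npath <- file.path(out_dir, "enrichment.tsv")
        write_tsv(as.data.frame(enr), npath)
        note("enrich", "executed", npath)
      } else note("enrich", "skipped (no gene sets)")
    } else {
      note("annotate", "skipped (no gene intervals)")
      note("enrich", "skipped (no gene sets)")
    }
  } else {
    note("rank", "skipped (no window coordinates)")
    note("annotate", "skipped (no window coordinates)")
    note("enrich", "skipped (no window coordinates)")
  }

  manifest$finished <- format(Sys.time())
  manifest$stages <- manifest$stages[pipeline_stages]
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: cfcnv %s, seed %s\n", x$version, x$seed))
  for (s in names(x$stages))
    cat(sprintf("  %-9s %s\n", s, x$stages[[s]]$status))
  invisible(x)
}
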