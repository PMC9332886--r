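# End-to-end pipeline: curate -> descriptors -> OFS -> split -> GA-MLR ->
# validation battery -> run directory of auditable artifacts.

#' Build a pipeline run configuration
#'
#' Every tunable of the pipeline in one replayable object. `activity_csv`
#' must have `compound_id`, `smiles` (unless a precomputed descriptor
#' matrix is supplied) and `ec50_nM` and/or `pec50`. When `descriptors_tsv`
#' is given, structure parsing and descriptor computation are skipped and
#' the matrix is injected at the objective-feature-selection stage.
#'
#' @param activity_csv path to the activity table.
#' @param descriptors_tsv optional path to a precomputed descriptor TSV.
#' @param outdir run directory to create.
#' @param activity_unit unit of the `ec50_nM` column.
#' @param descriptor_names descriptor pool to compute (default:
#'   [descriptor_pool()]).
#' @param with_3d embed 3D coordinates (required by `com_*` descriptors).
#' @param split_fraction,split_seed training share and split seed.
#' @param ofs list: `near_constant_prop`, `corr_threshold`.
#' @param ga list merged over [ga_config()] defaults, plus `k_max` and
#'   `breaking_eps`.
#' @param validation list: `lmo_fraction`, `lmo_iter`, `yrand_iter`,
#'   `quik_delta`, `resid_cutoff`, `seed`.
#' @return a `run_config` list.
#' @export
run_config <- function(activity_csv, descriptors_tsv = NULL,
                       outdir = "qsar_run", activity_unit = "nM",
                       descriptor_names = NULL, with_3d = FALSE,
                       split_fraction = 0.8, split_seed = 17L,
                       ofs = list(), ga = list(), validation = list()) {
  ofs <- utils::modifyList(
    list(near_constant_prop = 0.95, corr_threshold = 0.90), ofs)
  ga <- utils::modifyList(
    c(unclass(ga_config()), list(k_max = 6L, breaking_eps = 0.02)), ga)
  validation <- utils::modifyList(
    list(lmo_fraction = 0.3, lmo_iter = 1000, yrand_iter = 2000,
         quik_delta = 0.05, resid_cutoff = 3, seed = 1L), validation)
  structure(
    list(activity_csv = activity_csv, descriptors_tsv = descriptors_tsv,
         outdir = outdir, activity_unit = activity_unit,
         descriptor_names = descriptor_names, with_3d = with_3d,
         split_fraction = split_fraction, split_seed = split_seed,
         ofs = ofs, ga = ga, validation = validation),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full QSAR pipeline
#'
#' Executes curation, descriptor computation (or matrix injection),
#' objective feature selection, train/prediction splitting, GA-MLR subset
#' selection with breaking-point model sizing, OLS fitting and the complete
#' validation battery. All artifacts — curated table, descriptor matrix,
#' removal and GA logs, the model equation with standard errors, the
#' validation report and Williams/fit plot data, and the replayable
#' configuration — are written into the run directory.
#'
#' @param cfg a [run_config()] (or path to its YAML form).
#' @return invisibly, a list with `model`, `validation`, `chosen_k`,
#'   `curve`, `split`, `gt_pass` and `outdir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))

  records <- .stage("curate", {
    r <- read_activity_csv(cfg$activity_csv, cfg$activity_unit)
    if (is.null(cfg$descriptors_tsv)) {
      r <- curate(r)
      write_curation(r, cfg$outdir)
      r[r$kept, , drop = FALSE]
    } else r
  })

  dm <- .stage("descriptors", {
    if (!is.null(cfg$descriptors_tsv)) {
      read_descriptor_matrix(cfg$descriptors_tsv)
    } else {
      if (is.null(records$smiles))
        stop("activity CSV needs a 'smiles' column to compute descriptors")
      pool <- cfg$descriptor_names
      if (is.null(pool)) pool <- descriptor_pool()
      mols <- parse_molecules(records$smiles, records$compound_id,
                              with_3d = cfg$with_3d)
      m <- compute_matrix(mols, pool)
      write_descriptor_matrix(m, file.path(cfg$outdir, "descriptors.tsv"))
      m
    }
  })
  records <- records[match(dm$compound_ids, records$compound_id), ,
                     drop = FALSE]
  if (anyNA(records$compound_id))
    stop("descriptor matrix and activity table disagree on compound ids")
  y <- records$pec50

  ofs <- .stage("objective_feature_selection", {
    res <- objective_feature_selection(dm, cfg$ofs$near_constant_prop,
                                       cfg$ofs$corr_threshold)
    utils::write.csv(res$removal_log, file.path(cfg$outdir, "ofs_log.csv"),
                     row.names = FALSE)
    res
  })

  split <- .stage("split", {
    sp <- split_dataset(dm$compound_ids, cfg$split_fraction, cfg$split_seed)
    jsonlite::write_json(sp, file.path(cfg$outdir, "split.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    sp
  })
  tr <- match(split$train, dm$compound_ids)
  te <- match(split$test, dm$compound_ids)
  Xtr <- ofs$X[tr, , drop = FALSE]
  Xte <- ofs$X[te, , drop = FALSE]
  ytr <- y[tr]; yte <- y[te]

  sel <- .stage("ga_mlr", {
    cfg_ga <- do.call(ga_config, cfg$ga[names(cfg$ga) %in%
                                          names(formals(ga_config))])
    sizes <- ga_select_sizes(Xtr, ytr, cfg$ga$k_max, cfg_ga)
    utils::write.csv(sizes$curve,
                     file.path(cfg$outdir, "breaking_point.csv"),
                     row.names = FALSE)
    k <- breaking_point(sizes$curve$Q2_LOO, cfg$ga$breaking_eps)
    chosen <- sizes$results[[k]]
    utils::write.csv(chosen$log, file.path(cfg$outdir, "ga_log.csv"),
                     row.names = FALSE)
    list(chosen = chosen, k = k, curve = sizes$curve)
  })

  report <- .stage("validate", {
    Xs <- Xtr[, sel$chosen$subset, drop = FALSE]
    Xe <- Xte[, sel$chosen$subset, drop = FALSE]
    v <- cfg$validation
    rep <- validate_model(Xs, ytr, Xe, yte,
                          lmo_fraction = v$lmo_fraction,
                          lmo_iter = v$lmo_iter,
                          yrand_iter = v$yrand_iter,
                          quik_delta = v$quik_delta,
                          resid_cutoff = v$resid_cutoff, seed = v$seed)
    write_validation_report(rep, cfg$outdir)
    writeLines(format_model_equation(rep$model),
               file.path(cfg$outdir, "model.txt"))
    fitdat <- data.frame(
      compound_id = c(split$train, split$test),
      set = rep(c("train", "test"), c(length(tr), length(te))),
      observed = c(ytr, yte),
      predicted = c(rep$model$fitted, predict(rep$model, Xe)))
    utils::write.csv(fitdat, file.path(cfg$outdir, "fit_plot.csv"),
                     row.names = FALSE)
    rep
  })

  gt_pass <- if (!is.null(report$external))
    isTRUE(report$external$golbraikh_tropsha$pass) else NA
  invisible(list(model = report$model, validation = report,
                 chosen_k = sel$k, curve = sel$curve, split = split,
                 ofs_log = ofs$removal_log, gt_pass = gt_pass,
                 outdir = cfg$outdir))
}
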