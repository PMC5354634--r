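#' Run configuration
#'
#' Validated parameter bundle for [full_run()]. Either a synthetic dataset is
#' generated in place (`synthetic = TRUE`, the default, driven by `spec`), or
#' paths to a genome FASTA, gene BED, per-strand bedGraphs for both strains,
#' and a nucleosome table are supplied. Every analysis default equals the
#' standard parameter of the method: 201-bp pause window at 4 SD, 8-bp hybrid,
#' 500-bp nucleosome range, 61-bp display smoothing, 1000 resamples, 303 K,
#' short/long backtrack offsets 0-1 / 2-15.
#'
#' @param out_dir Output directory for tables and the manifest.
#' @param seed Seed for every stochastic step.
#' @param synthetic Generate the input dataset (default TRUE).
#' @param spec A `synthetic_spec` when `synthetic` (its seed is set from
#'   `seed` unless given explicitly).
#' @param paths Named list of input paths when `synthetic = FALSE`: genome,
#'   genes, wt_plus, wt_minus, dst1_plus, dst1_minus, nucleosomes.
#' @param nsd,width Pause-calling parameters.
#' @param temperature Kelvin.
#' @param pwm_offsets PWM window offsets.
#' @param bin_width Energy bin width (kJ/mol) for fraction/odds curves.
#' @param n_resamples Null-band resamples.
#' @param halfwidth Profile half-width around sites.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, synthetic = TRUE,
                       spec = NULL, paths = NULL,
                       nsd = 4, width = 201L, temperature = 303,
                       pwm_offsets = -10:5, bin_width = 1,
                       n_resamples = 1000L, halfwidth = 30L) {
  if (synthetic) {
    if (is.null(spec)) spec <- synthetic_spec(seed = seed)
  } else {
    need <- c("genome", "genes", "wt_plus", "wt_minus", "dst1_plus",
              "dst1_minus", "nucleosomes")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop("paths must name: ", paste(need, collapse = ", "))
    }
    missing <- !vapply(paths[need], file.exists, TRUE)
    if (any(missing)) stop("input not readable: ",
                           paste(unlist(paths[need][missing]), collapse = ", "))
  }
  stopifnot(nsd > 0, width %% 2 == 1, temperature > 0, bin_width > 0,
            n_resamples >= 1)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), synthetic = synthetic,
              spec = spec, paths = paths, nsd = nsd, width = as.integer(width),
              temperature = temperature, pwm_offsets = pwm_offsets,
              bin_width = bin_width, n_resamples = as.integer(n_resamples),
              halfwidth = as.integer(halfwidth))
  class(cfg) <- "run_config"
  cfg
}

#' Build a run configuration from a YAML file
#'
#' The file may hold any arguments of [run_config()]; a `spec:` block holds
#' [synthetic_spec()] arguments. Command-line style overrides can be supplied
#' as `...` and take precedence over the file.
#'
#' @param path YAML file path.
#' @param ... Overrides for [run_config()] arguments.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  if (!is.null(cfg$spec) && !inherits(cfg$spec, "synthetic_spec")) {
    cfg$spec <- do.call(synthetic_spec, cfg$spec)
  }
  do.call(run_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' End-to-end analysis run
#'
#' Orchestrates the whole pipeline on one dataset: pause calling for both
#' strains, energy profiles and delta-TEC scores, the nucleosome-distance,
#' mono-PWM and di-PWM predictors, a ROC/AUC comparison table, the averaged
#' delta-TEC profile around dst1 pauses with its resampling null band,
#' pause-fraction and log-odds curves, backtrack classification with the
#' long-fraction curve and logistic fit, and the mismatch fold-change report.
#' All tables are written as TSV under `out_dir` together with a manifest
#' (parameters, seed, versions) sufficient to re-run identically.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with every computed object (see the manifest for
#'   the file inventory).
#' @export
full_run <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)

  if (config$synthetic) {
    ds <- stage("simulate", generate_dataset(config$spec,
                                             temperature = config$temperature))
    tx <- ds$tx; profile <- ds$profile; nucs <- ds$nucleosomes
    wt <- ds$wt; dst1 <- ds$dst1
    res$truth <- ds$truth
  } else {
    ds <- stage("load-inputs", {
      genome <- read_fasta(config$paths$genome)
      genes <- read_bed_genes(config$paths$genes)
      tx <- build_concatenated_transcriptome(genome, genes)
      list(tx = tx,
           wt = read_bedgraph(config$paths$wt_plus, tx, "+", "WT") +
                read_bedgraph(config$paths$wt_minus, tx, "-", "WT"),
           dst1 = read_bedgraph(config$paths$dst1_plus, tx, "+", "dst1") +
                  read_bedgraph(config$paths$dst1_minus, tx, "-", "dst1"),
           nucleosomes = read_nucleosome_table(config$paths$nucleosomes))
    })
    tx <- ds$tx; nucs <- ds$nucleosomes
    wt <- ds$wt; dst1 <- ds$dst1
    attr(wt, "strain") <- "WT"; attr(dst1, "strain") <- "dst1"
    profile <- stage("energy-profile", energy_profile(tx, config$temperature))
  }
  res$tx <- tx; res$profile <- profile

  res$pauses_dst1 <- stage("call-pauses",
    call_pauses(dst1, tx, nsd = config$nsd, width = config$width))
  res$pauses_wt <- call_pauses(wt, tx, nsd = config$nsd, width = config$width)

  # expression filter (on the dst1 track) restricts predictor evaluation to
  # transcribed genes, where an absent pause is an informative negative
  ef <- stage("expression-filter", expression_filter(dst1, tx))
  res$expression <- ef
  eval_pos <- ef$positions
  labels <- logical(tx$n)
  labels[res$pauses_dst1$positions] <- TRUE

  scores <- stage("predictors", {
    nuc <- fit_pause_probability_by_distance(res$pauses_dst1, nucs, tx,
                                             pos = eval_pos)
    pwm_mono <- train_pwm(res$pauses_dst1, tx, config$pwm_offsets, "mono")
    pwm_di <- train_pwm(res$pauses_dst1, tx, config$pwm_offsets, "di")
    list(nucleosome = nuc$score,
         pwm_mono = score_positions(pwm_mono, tx)[eval_pos],
         pwm_di = score_positions(pwm_di, tx)[eval_pos],
         energy = profile$dtec_dst1[eval_pos])
  })
  res$scores <- scores

  res$roc <- stage("roc", {
    lab <- labels[eval_pos]
    data.frame(model = names(scores),
               auc = vapply(scores, function(s) roc_auc(s, lab)$auc, 0),
               n_pos = sum(lab & !is.na(scores$energy)),
               n = length(eval_pos), row.names = NULL)
  })

  res$profile_dtec <- stage("profiles", {
    d_sites <- res$pauses_dst1$positions[res$pauses_dst1$positions %in% eval_pos]
    obs <- average_profile(profile$dtec_dst1, d_sites, config$halfwidth)
    cand <- eval_pos[!is.na(profile$dtec_dst1[eval_pos])]
    band <- null_band(profile$dtec_dst1, obs$n_sites, cand,
                      halfwidth = config$halfwidth,
                      n_resamples = config$n_resamples, seed = config$seed)
    list(observed = obs, band = band)
  })

  res$pause_curve <- stage("pause-curve",
    pause_fraction_by_score(scores$energy, labels[eval_pos], config$bin_width))
  res$pause_fit <- stage("pause-fit",
    fit_log_odds(scores$energy, labels[eval_pos]))

  res$backtracks <- stage("backtrack", {
    calls <- classify_backtracks(res$pauses_dst1, res$pauses_wt, tx)
    kept <- calls$class != "excluded"
    fit <- if (length(unique(calls$class[kept])) == 2L) {
      fit_log_odds(profile$dtec_dst1[calls$dst1_position[kept]],
                   calls$class[kept] == "long")
    } else NULL
    list(calls = calls, fractions = backtrack_class_fractions(calls),
         curve = long_fraction_by_dtec(calls, profile$dtec_dst1,
                                       config$bin_width),
         fit = fit)
  })

  res$mismatch <- stage("mismatch", {
    mm <- build_energy_table("RNA:DNA-mismatch", config$temperature)
    pairs <- mismatch_dtec_distribution(tx, profile, mm, positions = eval_pos)
    if (is.null(res$backtracks$fit)) list(pairs = pairs, report = NULL)
    else list(pairs = pairs,
              report = predicted_fold_changes(pairs, res$pause_fit,
                                              res$backtracks$fit))
  })

  stage("write-outputs", write_run_outputs(res, config))
  invisible(res)
}

write_run_outputs <- function(res, config) {
  out <- function(name) file.path(config$out_dir, name)
  fw <- function(x, name) data.table::fwrite(x, out(name), sep = "\t")
  fw(res$roc, "roc_table.tsv")
  fw(res$pause_curve, "pause_fraction_by_dtec.tsv")
  fw(res$backtracks$calls, "backtrack_calls.tsv")
  fw(res$backtracks$curve, "long_fraction_by_dtec.tsv")
  fw(data.frame(offset = res$profile_dtec$observed$offsets,
                mean_dtec = res$profile_dtec$observed$mean,
                null_lower = res$profile_dtec$band$lower,
                null_upper = res$profile_dtec$band$upper),
     "dtec_profile_around_pauses.tsv")
  fw(res$mismatch$pairs, "mismatch_dtec_pairs.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("tecpause")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[c("nsd", "width", "temperature", "bin_width",
                          "n_resamples", "halfwidth")],
    pwm_offsets = config$pwm_offsets,
    synthetic = config$synthetic,
    spec = if (config$synthetic) unclass(config$spec)[
      !vapply(config$spec, is.function, TRUE)] else NULL,
    n_pauses_dst1 = length(res$pauses_dst1$positions),
    n_pauses_wt = length(res$pauses_wt$positions),
    backtrack_fractions = as.list(res$backtracks$fractions),
    auc = stats::setNames(as.list(res$roc$auc), res$roc$model),
    pause_fit = res$pause_fit[c("alpha", "beta")],
    backtrack_fit = if (!is.null(res$backtracks$fit))
      res$backtracks$fit[c("alpha", "beta")] else NULL,
    mismatch_folds = if (!is.null(res$mismatch$report))
      res$mismatch$report[c("pause_fold", "backtrack_fold", "combined_fold")]
      else NULL)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
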