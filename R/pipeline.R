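#' Pipeline configuration
#'
#' Configuration for the end-to-end study analogue: simulate a pooled
#' multi-component training cohort and a clinical EV cohort (HCC vs
#' cirrhosis), preprocess, train the autoencoder on the pooled cohort,
#' encode both cohorts, embed and screen latent features, classify, and run
#' the latent-perturbation attribution. Stage seeds are derived
#' deterministically from the global seed.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for stage artifacts.
#' @param stages Named logical vector toggling stages.
#' @param synth A [synth_config()] for the pooled training cohort.
#' @param clinical List with `n_hcc`, `n_cirrhosis`, `class` for the
#'   clinical EV cohort.
#' @param effect A [disease_effect()].
#' @param preprocess A [preprocess_config()].
#' @param ae_config An [ae_train_config()].
#' @param architecture An [ae_architecture()] or `NULL` for the default.
#' @param enet An [enet_spec()].
#' @param perturbation A [perturbation_spec()] or `NULL` to perturb the
#'   feature selected by the classifier.
#' @param embedding_method Backend for [embed_2d()].
#' @param n_permutations Label permutations for the null (0 disables).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            out_dir = tempfile("irlatent_run_"),
                            stages = c(synth = TRUE, preprocess = TRUE,
                                       ae = TRUE, latentstats = TRUE,
                                       clf = TRUE, sensitivity = TRUE),
                            synth = synth_config(seed = seed),
                            clinical = list(n_hcc = 9, n_cirrhosis = 16,
                                            class = "EV2"),
                            effect = disease_effect(),
                            preprocess = preprocess_config(),
                            ae_config = ae_train_config(),
                            architecture = NULL,
                            enet = enet_spec(),
                            perturbation = NULL,
                            embedding_method = "pca",
                            n_permutations = 0) {
  defaults <- c(synth = TRUE, preprocess = TRUE, ae = TRUE,
                latentstats = TRUE, clf = TRUE, sensitivity = TRUE)
  defaults[names(stages)] <- stages
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = defaults, synth = synth, clinical = clinical,
                 effect = effect, preprocess = preprocess,
                 ae_config = ae_config, architecture = architecture,
                 enet = enet, perturbation = perturbation,
                 embedding_method = embedding_method,
                 n_permutations = n_permutations),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields in the file override the defaults of
#' [pipeline_config()]; nested sections `synth`, `clinical`, `preprocess`,
#' `ae`, `enet`, `perturbation` override the corresponding constructor
#' arguments.
#'
#' @param file YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  seed <- y$seed %||% 1
  args <- list(seed = seed)
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  if (!is.null(y$synth)) {
    args$synth <- do.call(synth_config,
                          c(y$synth, list(seed = y$synth$seed %||% seed)))
  }
  if (!is.null(y$clinical)) args$clinical <- y$clinical
  if (!is.null(y$preprocess)) {
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  }
  if (!is.null(y$ae)) args$ae_config <- do.call(ae_train_config, y$ae)
  if (!is.null(y$enet)) args$enet <- do.call(enet_spec, y$enet)
  if (!is.null(y$perturbation)) {
    args$perturbation <- do.call(perturbation_spec, y$perturbation)
  }
  if (!is.null(y$embedding_method)) {
    args$embedding_method <- y$embedding_method
  }
  if (!is.null(y$n_permutations)) args$n_permutations <- y$n_permutations
  do.call(pipeline_config, args)
}

.stage_seed <- function(seed, offset) (seed * 101L + offset) %% 2147483647L

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: synthetic cohort generation (pooled multi-component
#' training cohort plus a clinical EV cohort), preprocessing, autoencoder
#' training on the pooled cohort, encoding of both cohorts, 2-D embedding
#' and group screening of the clinical latents, elastic-net LOOCV
#' classification, and latent-perturbation attribution of the selected
#' feature. Every stage writes its artifacts under `config$out_dir` and is
#' recorded in the returned manifest (file hashes, parameters, wall time).
#' Disabled stages, and stages whose upstream dependencies were skipped, are
#' recorded with the reason.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Object of class `run_manifest`; the full stage results are
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, out_dir = config$out_dir,
                   package_version = as.character(
                     utils::packageVersion("irlatent")),
                   stages = list())
  results <- list()
  files <- character(0)
  note <- function(stage, status, outputs = character(0), reason = NULL,
                   elapsed = NA_real_) {
    manifest$stages[[stage]] <<- list(
      status = status, outputs = as.list(outputs),
      hashes = as.list(unname(tools::md5sum(outputs))),
      reason = reason, seconds = elapsed)
    files <<- c(files, outputs)
    if (verbose) message(sprintf("[%s] %s", stage, status))
  }
  timed <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, elapsed = proc.time()[["elapsed"]] - t0)
  }
  skip_reason <- function(stage, reason) note(stage, "skipped", reason = reason)

  ## 1. synthetic cohorts -------------------------------------------------
  if (!config$stages[["synth"]]) {
    skip_reason("synth", "disabled in config")
  } else {
    tt <- timed({
      train_cfg <- config$synth
      train_cfg$seed <- .stage_seed(config$seed, 1L)
      train_set <- generate_cohort(train_cfg, effect = config$effect)
      clin_cfg <- clinical_cohort_config(
        n_hcc = config$clinical$n_hcc,
        n_cirrhosis = config$clinical$n_cirrhosis,
        class = config$clinical$class %||% "EV2",
        grid = config$synth$grid,
        patient_sd = config$synth$patient_sd,
        seed = .stage_seed(config$seed, 2L))
      clin_set <- generate_cohort(clin_cfg, effect = config$effect)
      list(train = train_set, clinical = clin_set)
    })
    results$synth <- tt$value
    f <- file.path(config$out_dir,
                   c("train_spectra.csv", "train_metadata.csv",
                     "clinical_spectra.csv", "clinical_metadata.csv"))
    write_spectrum_set(tt$value$train, f[1], f[2])
    write_spectrum_set(tt$value$clinical, f[3], f[4])
    note("synth", "ok", f, elapsed = tt$elapsed)
  }

  ## 2. preprocessing ------------------------------------------------------
  if (!config$stages[["preprocess"]]) {
    skip_reason("preprocess", "disabled in config")
  } else if (is.null(results$synth)) {
    skip_reason("preprocess", "upstream stage 'synth' unavailable")
  } else {
    tt <- timed(list(
      train = preprocess_set(results$synth$train, config$preprocess),
      clinical = preprocess_set(results$synth$clinical,
                                config$preprocess)))
    results$preprocess <- tt$value
    f <- file.path(config$out_dir,
                   c("train_processed.csv", "clinical_processed.csv"))
    write_processed(tt$value$train, f[1])
    write_processed(tt$value$clinical, f[2])
    note("preprocess", "ok", f, elapsed = tt$elapsed)
  }

  ## 3. autoencoder ----------------------------------------------------------
  if (!config$stages[["ae"]]) {
    skip_reason("ae", "disabled in config")
  } else if (is.null(results$preprocess)) {
    skip_reason("ae", "upstream stage 'preprocess' unavailable")
  } else {
    tt <- timed({
      model <- autoencoder(results$preprocess$train,
                           architecture = config$architecture,
                           config = config$ae_config,
                           seed = .stage_seed(config$seed, 3L))
      xhat <- predict(model, results$preprocess$train$x)
      report <- reconstruction_metrics(results$preprocess$train$x, xhat)
      lat_train <- encode(model, results$preprocess$train$x)
      lat_clin <- encode(model, results$preprocess$clinical$x)
      list(model = model, report = report, latent_train = lat_train,
           latent_clinical = lat_clin)
    })
    results$ae <- tt$value
    f <- file.path(config$out_dir,
                   c("latent_train.csv", "latent_clinical.csv",
                     "reconstruction_report.json", "training_history.csv"))
    utils::write.csv(data.frame(sample_id = rownames(tt$value$latent_train),
                                tt$value$latent_train),
                     f[1], row.names = FALSE)
    utils::write.csv(data.frame(
      sample_id = rownames(tt$value$latent_clinical),
      tt$value$latent_clinical), f[2], row.names = FALSE)
    jsonlite::write_json(list(mean_rmse = tt$value$report$mean_rmse,
                              sd_rmse = tt$value$report$sd_rmse),
                         f[3], auto_unbox = TRUE, digits = NA)
    utils::write.csv(tt$value$model$history, f[4], row.names = FALSE)
    note("ae", "ok", f, elapsed = tt$elapsed)
  }

  ## 4. latent statistics ----------------------------------------------------
  if (!config$stages[["latentstats"]]) {
    skip_reason("latentstats", "disabled in config")
  } else if (is.null(results$ae)) {
    skip_reason("latentstats", "upstream stage 'ae' unavailable")
  } else {
    tt <- timed({
      emb <- embed_2d(results$ae$latent_train,
                      method = config$embedding_method,
                      seed = .stage_seed(config$seed, 4L))
      tab <- compare_latent_features(
        results$ae$latent_clinical,
        results$synth$clinical$metadata$group)
      list(embedding = emb, table = tab)
    })
    results$latentstats <- tt$value
    f <- file.path(config$out_dir,
                   c("embedding.csv", "feature_tests.csv"))
    utils::write.csv(
      data.frame(sample_id = rownames(tt$value$embedding$coordinates),
                 tt$value$embedding$coordinates), f[1], row.names = FALSE)
    write_feature_table(tt$value$table, f[2])
    note("latentstats", "ok", f, elapsed = tt$elapsed)
  }

  ## 5. classification -------------------------------------------------------
  if (!config$stages[["clf"]]) {
    skip_reason("clf", "disabled in config")
  } else if (is.null(results$ae)) {
    skip_reason("clf", "upstream stage 'ae' unavailable")
  } else {
    tt <- timed(tryCatch(
      evaluate_latent_classifier(
        results$ae$latent_clinical,
        factor(results$synth$clinical$metadata$group,
               levels = c("cirrhosis", "HCC")),
        spec = config$enet,
        n_permutations = config$n_permutations,
        seed = .stage_seed(config$seed, 5L)),
      error = function(e) e))
    if (inherits(tt$value, "error")) {
      skip_reason("clf", conditionMessage(tt$value))
    } else {
      results$clf <- tt$value
      f <- file.path(config$out_dir,
                     c("cv_curve.csv", "oof_scores.csv",
                       "classifier_summary.json"))
      utils::write.csv(data.frame(lambda = tt$value$cv$lambda,
                                  mean_deviance = tt$value$cv$cvm,
                                  se = tt$value$cv$cvsd),
                       f[1], row.names = FALSE)
      utils::write.csv(
        data.frame(
          sample_id = rownames(results$ae$latent_clinical),
          group = results$synth$clinical$metadata$group,
          score = tt$value$cv$oof_scores), f[2], row.names = FALSE)
      jsonlite::write_json(
        list(auc = tt$value$roc$auc,
             ci_95 = tt$value$roc$ci_95,
             youden_threshold = tt$value$roc$youden_threshold,
             confusion = as.list(tt$value$roc$confusion),
             accuracy = tt$value$roc$accuracy,
             support = tt$value$cv$support,
             lambda_1se = tt$value$cv$lambda_1se,
             permutation_p = if (is.null(tt$value$permutation)) NULL
                             else tt$value$permutation$p_value),
        f[3], auto_unbox = TRUE, digits = NA)
      note("clf", "ok", f, elapsed = tt$elapsed)
    }
  }

  ## 6. sensitivity ------------------------------------------------------------
  if (!config$stages[["sensitivity"]]) {
    skip_reason("sensitivity", "disabled in config")
  } else if (is.null(results$ae)) {
    skip_reason("sensitivity", "upstream stage 'ae' unavailable")
  } else {
    pspec <- config$perturbation
    if (is.null(pspec)) {
      if (is.null(results$clf) || length(results$clf$cv$support) == 0) {
        feat <- if (!is.null(results$latentstats)) {
          results$latentstats$table$feature[1]
        } else {
          NULL
        }
        if (is.null(results$clf)) {
          skip_reason("sensitivity",
                      "no perturbation feature: stage 'clf' unavailable and none configured")
          feat <- NULL
        }
        if (!is.null(feat) && !is.null(results$clf)) {
          pspec <- perturbation_spec(feature = feat)
        }
      } else {
        pspec <- perturbation_spec(feature = results$clf$cv$support[1])
      }
    }
    if (!is.null(pspec)) {
      tt <- timed({
        prof <- latent_perturbation_profile(
          results$ae$model, results$ae$latent_clinical, pspec,
          wavenumber = results$preprocess$clinical$bin_centers)
        ann <- annotate_bands(prof)
        list(profile = prof, annotations = ann)
      })
      results$sensitivity <- tt$value
      f <- file.path(config$out_dir,
                     c("differential_profile.csv", "band_annotations.json"))
      utils::write.csv(
        data.frame(wavenumber = tt$value$profile$wavenumber,
                   mean = tt$value$profile$mean_profile,
                   ci_low = tt$value$profile$ci_low,
                   ci_high = tt$value$profile$ci_high),
        f[1], row.names = FALSE)
      jsonlite::write_json(tt$value$annotations, f[2], auto_unbox = TRUE,
                           digits = NA)
      note("sensitivity", "ok", f, elapsed = tt$elapsed)
    }
  }

  manifest$files <- as.list(files)
  manifest_file <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  out <- structure(manifest, class = "run_manifest")
  attr(out, "results") <- results
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run (seed", x$seed, ") ->", x$out_dir, "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")")
                else ""))
  }
  invisible(x)
}
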