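#' Default end-to-end run configuration
#'
#' Nested list of every knob of [run_full()], mirroring the study design:
#' a seven-accession panel with three plants per repetition and two
#' repetitions, 500 PRESS permutations with a 90/10 inner split over the
#' two-thirds calibration partition, a 94-individual F2 family, 1 cM
#' pseudomarkers, and 1000-permutation 95% LOD thresholds.
#'
#' @param seed Global seed recorded in the config; default 1.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    panel = list(n_plants = 3L, n_reps = 2L, n_readings = 1L,
                 noise_sd = 0.005),
    plsr = list(calibration_fraction = 2 / 3, max_ncomp = 15L,
                n_perm = 500L, inner_fraction = 0.9, scale = FALSE),
    f2 = list(n = 94L, noise_sd = 0.005,
              presets = c("H16_gcms", "Oct_gcms", "Tri_gcms")),
    qtl = list(step = 1, n_perm = 1000L, alpha = 0.05),
    out_dir = NULL
  )
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path Path to a YAML file.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        merge_cfg(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  merge_cfg(default_config(), user)
}

#' Predict F2 wax amounts from fitted PLSR models
#'
#' Applies one or more fitted models to the F2 leaf spectra, giving one
#' predicted amount per individual per wax, in a phenotype table directly
#' consumable by the QTL stage.
#'
#' @param models A single `plsr_model` or a named list of them (names =
#'   waxes).
#' @param f2_spectra A [spectra] object on the models' training grid.
#' @return Data frame: `sample_id` plus one predicted column per model.
#' @export
predict_f2 <- function(models, f2_spectra) {
  if (inherits(models, "plsr_model")) models <- list(predicted = models)
  out <- data.frame(sample_id = sample_ids(f2_spectra),
                    stringsAsFactors = FALSE)
  for (nm in names(models)) {
    out[[nm]] <- predict(models[[nm]], f2_spectra)
  }
  out
}

#' Run the full simulation-to-QTL pipeline
#'
#' Orchestrates the whole analysis on synthetic data: (1) build the three
#' standard signatures, detect their features and classify unique/shared
#' clusters; (2) simulate the accession panel, quality-filter, average
#' replicate readings, resample to 5 nm; (3) simulate the F2 family (true
#' GCMS-scale amounts per wax from the QTL presets) with paired leaf
#' spectra; (4) split the panel into calibration/validation stratified on
#' total wax, select components by PRESS, and fit one PLSR per wax;
#' (5) evaluate cross-validation (pooled PRESS held-out predictions) and
#' external validation (validation third plus the F2 family, matching the
#' study design); (6) predict F2 amounts from spectra and run the
#' Haley-Knott scan with permutation thresholds for both the
#' spectroscopy-predicted and the true simulated phenotypes.
#'
#' With `config$out_dir` set, all tables are also written as CSV (spectra,
#' phenotypes, map, genotypes, scan curves), models as JSON, and the
#' resolved config as YAML; the report lists the file manifest.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_run_config()].
#' @return Object of class `wax_run_report`: `ssv` (classification table),
#'   `split`, `models`, `press`, `evaluation` (per wax and dataset),
#'   `f2_predictions`, `qtl` (per trait: scan, threshold, interval, fit),
#'   `manifest`, `config`.
#' @export
run_full <- function(config = default_config()) {
  seed <- config$seed
  manifest <- character(0)

  # 1. standards and SSV classification (standards keep the native 1 nm
  # resolution; only the prediction models use the 5 nm grid)
  sigs <- lapply(c(H16 = "H16", Oct = "Oct", Tri = "Tri"),
                 build_standard_signature, grid = seq(350, 2500, by = 1))
  fsets <- lapply(sigs, detect_features)
  ssv <- classify_unique_shared(fsets)

  # 2. accession panel
  panel <- simulate_accession_panel(
    n_plants = config$panel$n_plants, n_reps = config$panel$n_reps,
    n_readings = config$panel$n_readings, noise_sd = config$panel$noise_sd,
    seed = seed
  )
  qc <- qc_filter(panel$spectra)
  sp <- qc$kept
  if (is.null(sp)) stop("pipeline stage 'panel QC': all spectra rejected",
                        call. = FALSE)
  if (config$panel$n_readings > 1L) {
    sp <- average_replicates(sp, "plant_id")
  }
  sp <- resample_5nm(sp)
  prof <- panel$profiles[match(sample_ids(sp), panel$profiles$sample_id), ]

  # 3. F2 family with spectra
  presets <- qtl_presets()[config$f2$presets]
  names(presets) <- vapply(presets, function(p) p$wax, character(1L))
  f2 <- simulate_f2_family(preset = presets, n = config$f2$n,
                           seed = seed + 1L)
  base <- leaf_baseline()
  f2_spec <- with_seed(seed + 2L, {
    do.call(cbind_spectra, lapply(seq_len(config$f2$n), function(i) {
      amt <- vapply(names(presets), function(w) max(0, f2$phenotypes[[w]][i]),
                    numeric(1L))
      simulate_leaf_spectrum(amt, baseline = base,
                             noise_sd = config$f2$noise_sd,
                             sample_id = f2$phenotypes$sample_id[i])
    }))
  })
  f2_spec <- resample_5nm(f2_spec)

  # 4. split + PLSR per wax
  total3 <- prof$H16 + prof$Oct + prof$Tri
  names(total3) <- prof$sample_id
  split <- stratified_split(total3,
                            calibration_fraction = config$plsr$calibration_fraction,
                            seed = seed + 3L)
  Xcal <- sp[split$calibration]
  Xval <- sp[split$validation]
  models <- list(); press <- list(); evaluation <- list()
  f2_true <- f2$phenotypes
  for (w in c("H16", "Oct", "Tri")) {
    ycal <- prof[[w]][match(split$calibration, prof$sample_id)]
    yval <- prof[[w]][match(split$validation, prof$sample_id)]
    pc <- select_components_press(Xcal, ycal,
                                  max_ncomp = config$plsr$max_ncomp,
                                  n_perm = config$plsr$n_perm,
                                  inner_fraction = config$plsr$inner_fraction,
                                  scale = config$plsr$scale,
                                  seed = seed + 4L)
    fit <- fit_plsr(Xcal, ycal, ncomp = pc$ncomp, scale = config$plsr$scale)
    cv <- evaluate_predictions(pc$held_out$predicted, pc$held_out$observed)
    cv$dataset <- "cross_validation"
    # external validation: held-out panel third plus the F2 family; the F2
    # reference is the leaf amount (phenotype truncated at zero), i.e. the
    # quantity the spectra were generated from
    ext_pred <- c(predict(fit, Xval), predict(fit, f2_spec))
    ext_obs <- c(yval, if (w %in% names(f2_true)) pmax(0, f2_true[[w]]) else
      rep(NA_real_, n_samples(f2_spec)))
    okk <- !is.na(ext_obs)
    ev <- evaluate_predictions(ext_pred[okk], ext_obs[okk])
    ev$dataset <- "validation"
    models[[w]] <- fit; press[[w]] <- pc
    evaluation[[w]] <- rbind(cv, ev)
    evaluation[[w]]$wax <- w
  }

  # 5. F2 predictions and QTL scans
  f2_pred <- predict_f2(models, f2_spec)
  probs <- genotype_probs(f2$genotypes, f2$map, step = config$qtl$step)
  qtl_out <- list()
  traits <- c(setNames(paste0(names(models), "_spectroscopy"),
                       paste0(names(models), "_spectroscopy")),
              setNames(paste0(names(presets), "_gcms"),
                       paste0(names(presets), "_gcms")))
  k <- 0L
  for (tr in names(traits)) {
    wax <- sub("_(spectroscopy|gcms)$", "", tr)
    y <- if (grepl("_spectroscopy$", tr)) f2_pred[[wax]] else f2_true[[wax]]
    scan <- hk_scan(probs, y)
    thr <- perm_threshold(probs, y, n_perm = config$qtl$n_perm,
                          alpha = config$qtl$alpha, seed = seed + 10L + k)
    scan$threshold <- as.numeric(thr)
    mx <- scan$positions[scan$max, ]
    qtl_out[[tr]] <- list(
      scan = scan, threshold = as.numeric(thr),
      interval = lod_interval(scan),
      fit = fit_qtl(probs, y, mx$chr, mx$pos_cM),
      significant = mx$lod >= as.numeric(thr)
    )
    k <- k + 1L
  }

  # 6. optional file outputs
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$out_dir, f)
    write_spectra(sp, pth("panel_spectra.csv"))
    write_phenotypes(prof, pth("panel_profiles.csv"))
    write_spectra(f2_spec, pth("f2_spectra.csv"))
    write_phenotypes(f2_true, pth("f2_gcms_phenotypes.csv"))
    write_phenotypes(f2_pred, pth("f2_predicted_phenotypes.csv"))
    write_genetic_map(f2$map, pth("map.csv"))
    write_genotypes(f2$genotypes, pth("genotypes.csv"))
    write.csv(ssv, pth("ssv_table.csv"), row.names = FALSE)
    for (w in names(models)) {
      write_plsr_model(models[[w]], pth(sprintf("plsr_%s.json", w)))
    }
    for (tr in names(qtl_out)) {
      write.csv(qtl_out[[tr]]$scan$positions,
                pth(sprintf("scan_%s.csv", tr)), row.names = FALSE)
    }
    yaml::write_yaml(config, pth("config.yaml"))
    manifest <- list.files(config$out_dir, full.names = TRUE)
  }

  structure(list(ssv = ssv, split = split, models = models, press = press,
                 evaluation = do.call(rbind, evaluation),
                 f2 = f2, f2_predictions = f2_pred, qtl = qtl_out,
                 manifest = manifest, config = config),
            class = "wax_run_report")
}

#' @export
print.wax_run_report <- function(x, ...) {
  cat("<wax_run_report>\n\nPrediction performance:\n")
  print(x$evaluation[, c("wax", "dataset", "r2", "rmse", "rel_rmse_pct")],
        row.names = FALSE)
  cat("\nQTL results (max-LOD position per trait):\n")
  for (tr in names(x$qtl)) {
    q <- x$qtl[[tr]]
    cat(sprintf("  %-18s chr %s @ %5.1f cM  LOD %5.2f (thr %4.2f)  %4.1f%% var  a=%6.3f d=%6.3f\n",
                tr, q$fit$chr, q$fit$pos_cM, q$fit$lod, q$threshold,
                q$fit$pct_var, q$fit$additive, q$fit$dominance))
  }
  invisible(x)
}
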