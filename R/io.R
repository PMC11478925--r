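#' Write / read the text FID interchange format
#'
#' A plain-text dialect: a header block of `# key: value` lines (kind,
#' n_points, dwell_s, bandwidth_hz, transmitter_mhz, field_strength_t,
#' te_ms, tr_ms, voxel_edge_cm, n_averages, n_water_averages), a column
#' header line, then one `index real imag` row per complex sample at 17
#' significant digits, so the round trip is lossless. CRLF and LF line
#' endings both parse.
#'
#' @param fid An `mrs_fid`.
#' @param path File path.
#' @return `write_fid`: the path, invisibly. `read_fid`: an `mrs_fid`.
#' @export
write_fid <- function(fid, path) {
  p <- fid$params
  hdr <- c(
    "# mrsdx FID v1",
    sprintf("# kind: %s", fid$kind),
    sprintf("# n_points: %d", p$n_points),
    sprintf("# dwell_s: %.17g", p$dwell_s),
    sprintf("# bandwidth_hz: %.17g", p$bandwidth_hz),
    sprintf("# transmitter_mhz: %.17g", p$transmitter_mhz),
    sprintf("# field_strength_t: %.17g", p$field_strength_t),
    sprintf("# te_ms: %.17g", p$te_ms),
    sprintf("# tr_ms: %.17g", p$tr_ms),
    sprintf("# voxel_edge_cm: %.17g", p$voxel_edge_cm),
    sprintf("# n_averages: %d", as.integer(p$n_averages)),
    sprintf("# n_water_averages: %d", as.integer(p$n_water_averages)),
    "index real imag"
  )
  body <- sprintf("%d %.17g %.17g", seq_along(fid$values),
                  Re(fid$values), Im(fid$values))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_fid
#' @export
read_fid <- function(path) {
  lines <- trimws(readLines(path), which = "right")
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (l in hdr_lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_]+):\\s*(.+)$", l))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  need <- c("kind", "n_points", "dwell_s", "bandwidth_hz", "transmitter_mhz",
            "te_ms", "tr_ms")
  missing <- setdiff(need, names(kv))
  if (length(missing)) {
    abort(paste0("malformed FID header; missing: ", paste(missing, collapse = ", ")))
  }
  n_points <- as.integer(kv$n_points)
  params <- acq_params(
    field_strength_t = as.numeric(kv$field_strength_t %||% 1.5),
    te_ms = as.numeric(kv$te_ms), tr_ms = as.numeric(kv$tr_ms),
    n_points = n_points, bandwidth_hz = as.numeric(kv$bandwidth_hz),
    voxel_edge_cm = as.numeric(kv$voxel_edge_cm %||% 2),
    n_averages = as.numeric(kv$n_averages %||% 128),
    n_water_averages = as.numeric(kv$n_water_averages %||% 8)
  )
  if (abs(params$dwell_s - as.numeric(kv$dwell_s)) > 1e-12 * params$dwell_s) {
    abort("header dwell_s inconsistent with bandwidth_hz")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  body <- body[!grepl("^index", body)]
  if (length(body) != n_points) {
    abort(sprintf("header n_points = %d but body has %d samples",
                  n_points, length(body)))
  }
  parts <- do.call(rbind, strsplit(body, "\\s+"))
  vals <- complex(real = as.numeric(parts[, 2]), imaginary = as.numeric(parts[, 3]))
  mrs_fid(vals, params, kv$kind)
}

#' Write a simulated cohort to disk
#'
#' One FID file pair per subject plus a manifest CSV (`subject`,
#' `tumour_type`, `fid_path`, `water_ref_path`).
#'
#' @param cohort A [sample_cohort()] tibble with `fid` and `water_ref`.
#' @param dir Output directory.
#' @return The manifest tibble, invisibly; also written as `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::pmap_dfr(
    list(cohort$subject, cohort$tumour_type, cohort$fid, cohort$water_ref),
    function(s, ty, fid, wref) {
      fp <- file.path(dir, paste0(s, "_fid.txt"))
      wp <- file.path(dir, paste0(s, "_wref.txt"))
      write_fid(fid, fp)
      write_fid(wref, wp)
      tibble(subject = s, tumour_type = ty, fid_path = fp, water_ref_path = wp)
    }
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Pipeline configuration
#'
#' Collects the stage settings and seeds for a full synthetic run:
#' training/test cohort sizes, fit configuration, QC criteria, classifier
#' options. Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n_train,n_test Named subjects-per-class vectors. Defaults mirror
#'   a post-QC case mix of 12/4/18 (training) and 16/3/14 (test) for
#'   PA/EP/MB.
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_points Complex points per FID.
#' @param fit Named list overriding [fit_config()] defaults.
#' @param qc Named list overriding [qc_criteria()] defaults.
#' @param classifier Named list: `lambda`, `prior`, `use_qc_features`.
#' @param qc_enabled Apply spectrum-level QC before classification.
#' @param out_dir Output directory (tables and model JSON are written
#'   there when not `NULL`).
#' @return A `mrs_pipeline_config` list.
#' @export
pipeline_config <- function(n_train = c(PA = 12, EP = 4, MB = 18),
                            n_test = c(PA = 16, EP = 3, MB = 14),
                            seed = 1, n_points = 2048,
                            fit = list(), qc = list(),
                            classifier = list(lambda = 0.1, prior = "uniform",
                                              use_qc_features = TRUE),
                            qc_enabled = TRUE, out_dir = NULL) {
  structure(list(
    n_train = as.list(n_train), n_test = as.list(n_test),
    seed = as.integer(seed), n_points = as.integer(n_points),
    fit = fit, qc = qc, classifier = classifier,
    qc_enabled = qc_enabled, out_dir = out_dir
  ), class = "mrs_pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `mrs_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, list(
    n_train = unlist(raw$n_train), n_test = unlist(raw$n_test),
    seed = raw$seed, n_points = raw$n_points,
    fit = raw$fit %||% list(), qc = raw$qc %||% list(),
    classifier = raw$classifier, qc_enabled = raw$qc_enabled,
    out_dir = raw$out_dir
  ))
}

quantify_cohort <- function(cohort, basis, cfg) {
  quants <- list()
  features <- list()
  for (i in seq_len(nrow(cohort))) {
    qs <- quantify_subject(cohort$fid[[i]], cohort$water_ref[[i]], basis, cfg)
    quants[[cohort$subject[i]]] <- qs$quant
    features[[i]] <- mutate(qs$features, subject = cohort$subject[i],
                            .before = 1)
  }
  list(quants = quants, features = bind_rows(features))
}

features_wide <- function(feature_long, cohort) {
  wide <- tidyr::pivot_wider(
    select(feature_long, "subject", "feature", "value"),
    names_from = "feature", values_from = "value"
  )
  left_join(wide, select(cohort, "subject", "tumour_type"), by = "subject")
}

#' Run the full synthetic evaluation pipeline
#'
#' Executes the stages in acquisition order: simulate training and test
#' cohorts, preprocess (eddy-current correction, Fourier transform,
#' automatic phasing), fit the linear-combination model, apply
#' quality-control gates and feature selection on the training cohort,
#' train the discriminant classifier, classify the test cohort
#' prospectively, and tabulate the confusion matrix and accuracy. Rerunning
#' with an identical configuration reproduces identical outputs; every
#' artifact is stamped with the configuration hash and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `mrs_pipeline_run`: `manifest` (config hash,
#'   seed, stage record), `model`, `qc_report`, `selected_features`,
#'   `train_features`, `test_features`, `features_long` (per-subject
#'   feature concentrations with CRLBs), `evaluation`
#'   (see [evaluate_classifier()]), `predictions`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- "simulate"
  result <- tryCatch({
    basis <- build_default_basis()
    params <- acq_params(n_points = config$n_points)
    cps <- default_class_params()
    train <- sample_cohort(cps, unlist(config$n_train), basis, params,
                           seed = config$seed)
    test <- sample_cohort(cps, unlist(config$n_test), basis, params,
                          seed = config$seed + 1000L)
    test$subject <- sub("^S", "P", test$subject)

    stage <- "quantify"
    cfg <- do.call(fit_config, config$fit)
    qtrain <- quantify_cohort(train, basis, cfg)
    qtest <- quantify_cohort(test, basis, cfg)

    stage <- "qc"
    crit <- do.call(qc_criteria, config$qc)
    qc_train <- cohort_qc(qtrain$quants, crit)
    qc_test <- cohort_qc(qtest$quants, crit)
    if (isTRUE(config$qc_enabled)) {
      keep_train <- qc_train$subject[qc_train$pass]
      keep_test <- qc_test$subject[qc_test$pass]
    } else {
      keep_train <- qc_train$subject
      keep_test <- qc_test$subject
    }
    train_feat_long <- filter(qtrain$features, .data$subject %in% keep_train)
    test_feat_long <- filter(qtest$features, .data$subject %in% keep_test)
    selected <- if (isTRUE(config$classifier$use_qc_features)) {
      select_features(train_feat_long, crit)
    } else {
      unique(train_feat_long$feature)
    }

    stage <- "train"
    train_wide <- features_wide(train_feat_long, train)
    model <- train_lda(
      train_wide, label = "tumour_type", features = selected,
      prior = config$classifier$prior %||% "uniform",
      lambda = config$classifier$lambda %||% 0.1
    )

    stage <- "classify"
    test_wide <- features_wide(test_feat_long, test)
    evaluation <- evaluate_classifier(model, test_wide)

    list(
      model = model,
      qc_report = bind_rows(
        mutate(qc_train, cohort = "train"),
        mutate(qc_test, cohort = "test")
      ),
      selected_features = selected,
      train_features = train_wide,
      test_features = test_wide,
      features_long = bind_rows(
        mutate(train_feat_long, cohort = "train"),
        mutate(test_feat_long, cohort = "test")
      ),
      evaluation = evaluation,
      predictions = evaluation$predictions
    )
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    stages = c("simulate", "quantify", "qc", "train", "classify"),
    n_train_used = nrow(result$train_features),
    n_test_used = nrow(result$test_features)
  )
  run <- structure(c(list(manifest = manifest), result),
                   class = "mrs_pipeline_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(run$predictions,
                     file.path(config$out_dir, "predictions.csv"))
    readr::write_csv(run$qc_report, file.path(config$out_dir, "qc_report.csv"))
    readr::write_csv(run$train_features,
                     file.path(config$out_dir, "train_features.csv"))
    readr::write_csv(run$test_features,
                     file.path(config$out_dir, "test_features.csv"))
    readr::write_csv(run$features_long,
                     file.path(config$out_dir, "features_with_crlb.csv"))
    jsonlite::write_json(run$selected_features,
                         file.path(config$out_dir, "selected_features.json"))
    jsonlite::write_json(
      serialize_lda(run$model),
      file.path(config$out_dir, "model.json"),
      auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.mrs_pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<mrs_pipeline_run> seed %d, %d train / %d test after QC, accuracy %d%%\n",
    x$manifest$seed, x$manifest$n_train_used, x$manifest$n_test_used,
    x$evaluation$accuracy_pct
  ))
  invisible(x)
}

#' Serialize / restore a discriminant model as JSON-ready lists
#'
#' @param model An `mrs_lda`.
#' @return `serialize_lda`: a plain list (write with
#'   [jsonlite::write_json()]); `deserialize_lda`: an `mrs_lda`.
#' @export
serialize_lda <- function(model) {
  list(
    features = model$features,
    mu = as.list(stats::setNames(as.numeric(model$mu), model$features)),
    sigma = as.list(stats::setNames(as.numeric(model$sigma), model$features)),
    classes = model$classes,
    class_means = apply(model$class_means, 1, as.numeric, simplify = FALSE),
    Sigma = apply(model$Sigma, 1, as.numeric, simplify = FALSE),
    priors = as.list(stats::setNames(as.numeric(model$priors), model$classes)),
    projection = apply(model$proj, 1, as.numeric, simplify = FALSE),
    lambda = model$lambda,
    n = model$n
  )
}

#' @rdname serialize_lda
#' @param x A list produced by `serialize_lda` (e.g. read back from JSON).
#' @export
deserialize_lda <- function(x) {
  p <- length(x$features)
  K <- length(x$classes)
  m_k <- do.call(rbind, lapply(x$class_means, as.numeric))
  Sigma <- do.call(rbind, lapply(x$Sigma, as.numeric))
  proj <- do.call(rbind, lapply(x$projection, as.numeric))
  Sigma_inv <- solve(Sigma)
  priors <- stats::setNames(as.numeric(unlist(x$priors)), x$classes)
  W <- Sigma_inv %*% t(m_k)
  b <- -0.5 * colSums(t(m_k) * W) + log(priors)
  structure(list(
    features = unlist(x$features),
    mu = stats::setNames(as.numeric(unlist(x$mu)), x$features),
    sigma = stats::setNames(as.numeric(unlist(x$sigma)), x$features),
    classes = unlist(x$classes), class_means = m_k, Sigma = Sigma,
    Sigma_inv = Sigma_inv, priors = priors, W = W, b = b,
    proj = proj, df_class_means = m_k %*% proj,
    lambda = x$lambda, n = x$n, counts = NA_real_,
    train_scores = tibble(subject = character(), label = character(),
                          DF1 = numeric(), DF2 = numeric())
  ), class = "mrs_lda")
}

#' Write / read a certainty table CSV
#'
#' Columns: `rater`, `case`, `stage`, `cert_PA`, `cert_EP`, `cert_MB`,
#' `truth`.
#'
#' @param tbl Certainty tibble.
#' @param path CSV path.
#' @return The path / the tibble.
#' @export
write_certainty_csv <- function(tbl, path) {
  check_certainty_table(tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_certainty_csv
#' @export
read_certainty_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  check_certainty_table(tbl)
  tbl
}
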