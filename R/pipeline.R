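#' Pipeline configuration
#'
#' Collects everything the end-to-end run needs: the two ROI boxes, the
#' high-pass kernel, the SVM hyperparameters, the target screening
#' sensitivity and the physical pixel size. `roi_right`/`roi_left` may be
#' `NULL`, in which case images are assumed to be pre-cropped ROIs.
#'
#' @param roi_right,roi_left [roi_box()] objects or `NULL`.
#' @param kernel_size High-pass averaging window (see [highpass()]).
#' @param gamma,cost RBF-SVM hyperparameters.
#' @param target_sensitivity Sensitivity targeted when choosing the cutoff.
#' @param pixel_spacing_mm Physical pixel size (default 300 dpi).
#' @return A list of class `mcw_config`.
#' @export
pipeline_config <- function(roi_right = NULL, roi_left = NULL,
                            kernel_size = 101L, gamma = 1, cost = 1,
                            target_sensitivity = 0.90,
                            pixel_spacing_mm = 25.4 / 300) {
  for (b in list(roi_right, roi_left)) {
    if (!is.null(b) && !inherits(b, "mcw_roi_box")) {
      abort("roi boxes must be NULL or created by roi_box()")
    }
  }
  structure(
    list(
      roi_right = roi_right, roi_left = roi_left,
      kernel_size = as.integer(kernel_size),
      gamma = gamma, cost = cost,
      target_sensitivity = target_sensitivity,
      pixel_spacing_mm = pixel_spacing_mm
    ),
    class = "mcw_config"
  )
}

#' Read a pipeline configuration from a key-value text file
#'
#' The file holds `key = value` lines (`#` comments and blank lines are
#' ignored). Recognized keys: `roi.right` and `roi.left` as
#' `top,left,height,width`, `enhance.kernel_size`, `svm.gamma`, `svm.cost`,
#' `svm.target_sensitivity`, `pixel_spacing_mm`. Parse errors are fatal and
#' report the offending line number.
#'
#' @param path Config file path.
#' @return An `mcw_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  cfg <- pipeline_config()
  parse_box <- function(value, side, lineno) {
    parts <- suppressWarnings(as.numeric(strsplit(value, ",")[[1L]]))
    if (length(parts) != 4L || anyNA(parts)) {
      abort(paste0(
        "config line ", lineno, ": roi.", side,
        " must be 'top,left,height,width'"
      ))
    }
    roi_box(parts[1L], parts[2L], parts[3L], parts[4L], side = side)
  }
  parse_num <- function(value, key, lineno) {
    x <- suppressWarnings(as.numeric(value))
    if (is.na(x)) abort(paste0("config line ", lineno, ": ", key, " must be numeric"))
    x
  }
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (line == "") next
    if (!grepl("=", line, fixed = TRUE)) {
      abort(paste0("config line ", i, ": expected 'key = value', got '", lines[i], "'"))
    }
    key <- trimws(sub("=.*$", "", line))
    value <- trimws(sub("^[^=]*=", "", line))
    switch(key,
      "roi.right" = cfg$roi_right <- parse_box(value, "right", i),
      "roi.left" = cfg$roi_left <- parse_box(value, "left", i),
      "enhance.kernel_size" = cfg$kernel_size <- as.integer(parse_num(value, key, i)),
      "svm.gamma" = cfg$gamma <- parse_num(value, key, i),
      "svm.cost" = cfg$cost <- parse_num(value, key, i),
      "svm.target_sensitivity" = cfg$target_sensitivity <- parse_num(value, key, i),
      "pixel_spacing_mm" = cfg$pixel_spacing_mm <- parse_num(value, key, i),
      abort(paste0("config line ", i, ": unknown key '", key, "'"))
    )
  }
  cfg
}

run_stage <- function(stage, side, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      paste0("stage '", stage, "' (", side, " side): ", conditionMessage(e)),
      parent = e
    )
  })
}

#' Measure one side of the mandible
#'
#' Runs the full measurement chain on one ROI: crop (if a box is given),
#' enhancement and segmentation, largest connected component, chessboard
#' distance transform, dynamic-programming medial-axis trace, disc-envelope
#' margin reconstruction, quadratic fit to the upper margin, and
#' perpendicular width measurement. Stage errors are re-raised with the
#' stage name and side.
#'
#' @param image A grayscale image (full radiograph or pre-cropped ROI).
#' @param side `"right"` or `"left"`.
#' @param config An [pipeline_config()] list.
#' @param audit_dir If non-`NULL`, intermediate stage images and curves are
#'   written there for visual audit.
#' @return A list with the intermediates: `roi`, `segmentation`, `mask`,
#'   `dmap`, `trace`, `margins`, `poly`, `profile`.
#' @export
measure_side <- function(image, side = c("right", "left"),
                         config = pipeline_config(), audit_dir = NULL) {
  side <- arg_match(side)
  box <- if (side == "right") config$roi_right else config$roi_left
  roi <- if (is.null(box)) {
    as_gray_image(image)
  } else {
    run_stage("crop_roi", side, crop_roi(image, box))
  }
  seg <- run_stage("segment_cortex", side, segment_cortex(roi, config$kernel_size))
  mask <- run_stage("largest_component", side, largest_component(seg$binary))
  dmap <- run_stage("endf", side, endf(mask))
  trace <- run_stage("trace_medial_axis", side, trace_medial_axis(dmap))
  margins <- run_stage("disc_envelope", side, disc_envelope(trace))
  poly <- run_stage("fit_upper_polynomial", side, fit_upper_polynomial(margins))
  profile <- run_stage(
    "measure_widths", side,
    measure_widths(margins, poly, spacing_mm = config$pixel_spacing_mm, side = side)
  )
  out <- list(
    roi = roi, segmentation = seg, mask = mask, dmap = dmap,
    trace = trace, margins = margins, poly = poly, profile = profile
  )
  if (!is.null(audit_dir)) write_audit(out, side, audit_dir)
  out
}

write_audit <- function(stages, side, audit_dir) {
  dir.create(audit_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(audit_dir, side)
  norm01 <- function(m) {
    r <- range(m)
    if (diff(r) == 0) m * 0 else (m - r[1L]) / diff(r) * 255
  }
  write_gray_image(stages$roi, paste0(pre, "_1_roi.png"))
  write_gray_image(stages$segmentation$equalized, paste0(pre, "_2_equalized.png"))
  write_gray_image(stages$segmentation$otsu_mask * 255, paste0(pre, "_3_otsu_mask.png"))
  write_gray_image(norm01(stages$segmentation$highpass), paste0(pre, "_4_highpass.png"))
  write_gray_image(stages$mask * 255, paste0(pre, "_5_object.png"))
  write_gray_image(norm01(stages$dmap), paste0(pre, "_6_endf.png"))
  write.csv(stages$trace, paste0(pre, "_trace.csv"), row.names = FALSE)
  write.csv(stages$margins, paste0(pre, "_margins.csv"), row.names = FALSE)
  write.csv(stages$profile, paste0(pre, "_widths.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Run the end-to-end pipeline on one subject
#'
#' Measures both sides, reduces the two width profiles to the
#' `(mean, variance)` feature vector, and — when a trained model is
#' supplied — scores and classifies the subject at the model's operating
#' cutoff. The whole chain is deterministic: the same images and
#' configuration always produce the same result.
#'
#' @param image_right,image_left Grayscale images of the two sides.
#' @param config An [pipeline_config()] list.
#' @param model Optional `mcw_svm` model for scoring.
#' @param subject_id Identifier carried into the result.
#' @param audit_dir Optional directory for intermediate stage output.
#' @return A one-row tibble with the feature vector, per-side summaries,
#'   stage timings and (with a model) `score` and `predicted`, plus
#'   list-columns `profile_right`, `profile_left`.
#' @examples
#' rib <- render_ribbon(ribbon_spec(true_width_px = 30, seed = 2))
#' run_subject(rib$image, rib$image)
#' @export
run_subject <- function(image_right, image_left, config = pipeline_config(),
                        model = NULL, subject_id = "subject", audit_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  right <- measure_side(image_right, "right", config, audit_dir)
  t1 <- proc.time()[["elapsed"]]
  left <- measure_side(image_left, "left", config, audit_dir)
  t2 <- proc.time()[["elapsed"]]
  features <- extract_features(right$profile, left$profile)
  out <- tibble(
    subject_id = subject_id,
    mean_width_mm = features$mean_width_mm,
    var_width_mm2 = features$var_width_mm2,
    mean_width_right_mm = mean(right$profile$width_mm),
    mean_width_left_mm = mean(left$profile$width_mm),
    n_columns_right = nrow(right$profile),
    n_columns_left = nrow(left$profile),
    seconds_right = t1 - t0,
    seconds_left = t2 - t1,
    profile_right = list(right$profile),
    profile_left = list(left$profile)
  )
  if (!is.null(model)) {
    out$score <- decision_score(model, features)
    out$predicted <- ifelse(out$score >= model$cutoff, 1, -1)
  }
  out
}

#' Stratified train/test split of a feature cohort
#'
#' Splits a labeled feature table into training and testing subsets,
#' preserving the class mix (each class contributes proportionally to the
#' training set, largest-remainder rounding).
#'
#' @param features A data frame with a `label` column.
#' @param n_train Number of training rows.
#' @param seed RNG seed for the shuffle.
#' @return A list with `train` and `test` tibbles.
#' @export
train_test_split <- function(features, n_train = 60L, seed = 1L) {
  features <- as_tibble(features)
  if (!"label" %in% names(features)) abort("features must have a 'label' column")
  n <- nrow(features)
  if (n_train < 1L || n_train >= n) abort("n_train must be in [1, nrow - 1]")
  withr::with_seed(seed, {
    y <- normalize_labels(features$label)
    take <- integer(0)
    counts <- table(y)
    exact <- n_train * as.numeric(counts) / n
    base <- floor(exact)
    rem <- n_train - sum(base)
    extra_order <- order(exact - base, decreasing = TRUE)
    base[extra_order[seq_len(rem)]] <- base[extra_order[seq_len(rem)]] + 1
    for (k in seq_along(counts)) {
      cls <- as.numeric(names(counts))[k]
      idx <- which(y == cls)
      take <- c(take, sample(idx, base[k]))
    }
    list(train = features[sort(take), ], test = features[-sort(take), ])
  })
}

check_feature_csv <- function(df, path, need_label = TRUE) {
  need <- c("subject_id", "mean_width_mm", "var_width_mm2", if (need_label) "label")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(paste0(
      "feature file ", path, " is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Command-level train / test / predict operations
#'
#' Thin file-to-file wrappers around the classifier: `cmd_train()` fits the
#' RBF-SVM on a feature CSV, chooses the operating cutoff on the training
#' scores, and serializes the model as JSON; `cmd_test()` scores a feature
#' CSV with a stored model and writes the screening metrics as JSON;
#' `cmd_predict()` runs the imaging pipeline on image pairs and writes
#' feature/score/label rows. The command-line interface in
#' `system.file("cli", "mcwscreen.R", package = "mcwscreen")` calls these.
#'
#' Feature CSVs carry `subject_id, mean_width_mm, var_width_mm2, label`
#' with labels coded -1/+1 or 0/1 (1 = low bone mineral density).
#'
#' @param features_csv Path to a feature CSV.
#' @param model_path Path of the model JSON (written or read).
#' @param gamma,cost,target_sensitivity,scale Training parameters.
#' @param out_json,out_csv Output paths.
#' @param pairs A data frame with columns `subject_id`, `right`, `left`
#'   (image file paths) for `cmd_predict()`.
#' @param config An [pipeline_config()] for `cmd_predict()`.
#' @return `cmd_train()` the fitted model (invisibly); `cmd_test()` the
#'   metrics tibble (invisibly); `cmd_predict()` the result tibble
#'   (invisibly).
#' @export
cmd_train <- function(features_csv, model_path, gamma = 1, cost = 1,
                      target_sensitivity = 0.90, scale = TRUE) {
  df <- read.csv(features_csv, stringsAsFactors = FALSE)
  check_feature_csv(df, features_csv)
  model <- train_svm(df,
    feature_cols = c("mean_width_mm", "var_width_mm2"),
    cost = cost, gamma = gamma, scale = scale
  )
  scores <- decision_score(model, df)
  op <- choose_cutoff(scores, df$label, target_sensitivity)
  model <- set_cutoff(model, op, target_sensitivity)
  write_svm_model(model, model_path)
  invisible(model)
}

#' @rdname cmd_train
#' @export
cmd_test <- function(model_path, features_csv, out_json = NULL) {
  model <- read_svm_model(model_path)
  df <- read.csv(features_csv, stringsAsFactors = FALSE)
  check_feature_csv(df, features_csv)
  pred <- predict(model, df)
  metrics <- screening_metrics(pred, df$label)
  if (!is.null(out_json)) {
    counts <- attr(metrics, "counts")
    payload <- list(
      metrics = lapply(seq_len(nrow(metrics)), function(i) {
        list(
          estimate = metrics$estimate[i],
          conf_low = metrics$conf_low[i],
          conf_high = metrics$conf_high[i]
        )
      }),
      counts = as.list(counts),
      cutoff = model$cutoff,
      n = nrow(df)
    )
    names(payload$metrics) <- metrics$metric
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(metrics)
}

#' @rdname cmd_train
#' @export
cmd_predict <- function(model_path, pairs, config = pipeline_config(),
                        out_csv = NULL) {
  model <- if (is.null(model_path)) NULL else read_svm_model(model_path)
  need <- c("subject_id", "right", "left")
  if (!all(need %in% names(pairs))) {
    abort("`pairs` must have columns subject_id, right, left")
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- read_gray_image(pairs$right[i])
    l <- read_gray_image(pairs$left[i])
    res <- run_subject(r, l, config, model, subject_id = pairs$subject_id[i])
    res[setdiff(names(res), c("profile_right", "profile_left"))]
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) {
    write.csv(as.data.frame(out), out_csv, row.names = FALSE)
  }
  invisible(out)
}
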