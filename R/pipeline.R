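#' Names of all 50 features
#' @return Character vector: 15 phonatory then 35 time-frequency names.
#' @export
all_feature_names <- function() c(phonatory_feature_names(), tf_feature_names())

#' Pipeline configuration
#'
#' Defaults follow the standard protocol: decimation factor 5 (44100 ->
#' 8820 Hz), z-scoring, 150 ms mid-phonation segment, pitch floor/ceiling
#' 75/600 Hz, Choi-Williams sigma 1, the 7-band scheme, alpha 0.05, 10-fold
#' CV with training-fold upsampling at a 50% threshold.
#'
#' @param n_per_group,sex,seed Synthetic-cohort settings (used when no
#'   `input_dir` is given).
#' @param input_dir Optional directory with `metadata.csv` + WAV files.
#' @param out_dir Optional output directory for feature table, selection
#'   tables, CV reports and a run manifest.
#' @param factor,duration Preprocessing settings.
#' @param pitch_floor,pitch_ceiling Pitch bounds (Hz).
#' @param sigma Choi-Williams kernel parameter.
#' @param alpha Selection threshold.
#' @param cv A [cv_config()] (its seed is overridden by `seed`).
#' @return List of class `bv_run_config`.
#' @export
run_config <- function(n_per_group = 10, sex = "F", seed = 1,
                       input_dir = NULL, out_dir = NULL,
                       factor = 5L, duration = 0.150,
                       pitch_floor = 75, pitch_ceiling = 600,
                       sigma = 1, alpha = 0.05, cv = cv_config()) {
  cv$seed <- as.integer(seed)
  structure(list(n_per_group = n_per_group, sex = sex, seed = seed,
                 input_dir = input_dir, out_dir = out_dir, factor = factor,
                 duration = duration, pitch_floor = pitch_floor,
                 pitch_ceiling = pitch_ceiling, sigma = sigma, alpha = alpha,
                 cv = cv),
            class = "bv_run_config")
}

#' Read a recorded cohort from disk
#'
#' Expects `metadata.csv` with columns subject_id, sex, group, vowel, path
#' (paths relative to `dir` or absolute).
#'
#' @param dir Directory containing the metadata and WAV files.
#' @return List of `bv_recording`.
#' @export
read_cohort <- function(dir) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = "character")  # "F" must stay a string
  need <- c("subject_id", "sex", "group", "vowel", "path")
  if (!all(need %in% names(md)))
    stop("metadata.csv must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(md)), function(i) {
    p <- md$path[i]
    if (!file.exists(p)) p <- file.path(dir, p)
    w <- read_wav(p)
    vowel_recording(w$samples, w$rate, subject_id = md$subject_id[i],
                    vowel = md$vowel[i], sex = md$sex[i],
                    group = md$group[i])
  })
}

#' Extract the 50-feature table from a list of recordings
#'
#' Preprocesses each recording (decimate, z-score, cut) and computes the 15
#' phonatory + 35 time-frequency features. Per-recording failures are logged
#' and produce NA rows; the run aborts if more than `max_error_frac` of the
#' recordings fail.
#'
#' @param recordings List of `bv_recording` (e.g. from [make_cohort()] or
#'   [read_cohort()]).
#' @param config A [run_config()].
#' @param progress Print one line per recording.
#' @return A data.frame: subject_id, sex, vowel, group + 50 feature columns.
#' @export
extract_features <- function(recordings, config = run_config(),
                             progress = FALSE, max_error_frac = 0.2) {
  feats <- all_feature_names()
  n_err <- 0L
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    if (progress)
      message(sprintf("[%d/%d] %s/%s", i, length(recordings),
                      rec$subject_id, rec$vowel))
    vals <- tryCatch({
      seg <- preprocess_recording(rec, factor = config$factor,
                                  duration = config$duration)
      ph <- suppressWarnings(
        phonatory_features(seg, floor = config$pitch_floor,
                           ceiling = config$pitch_ceiling))
      tf <- suppressWarnings(extract_tf_features(seg, sigma = config$sigma))
      c(unlist(ph), tf)
    }, error = function(e) {
      warning("feature extraction failed for ", rec$subject_id, "/",
              rec$vowel, ": ", conditionMessage(e))
      n_err <<- n_err + 1L
      stats::setNames(rep(NA_real_, length(feats)), feats)
    })
    df <- data.frame(subject_id = rec$subject_id, sex = rec$sex,
                     vowel = rec$vowel, group = rec$group)
    df[feats] <- as.numeric(vals[feats])
    df
  })
  if (n_err / length(recordings) > max_error_frac)
    stop(n_err, " of ", length(recordings), " recordings failed (> ",
         round(100 * max_error_frac), "%)")
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' Synthesizes (or reads) a cohort, extracts the 50-feature table, screens
#' features per comparison at `alpha`, and runs the cross-validated
#' five-model evaluation per comparison, all with one seed. When
#' `config$out_dir` is set, writes `features.csv`, per-comparison
#' `selection_<cmp>.csv` and `cv_<cmp>.csv`, and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return List of class `bv_run`: `features`, `selection` (per comparison),
#'   `cv` (per comparison), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  recordings <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    make_cohort(config$n_per_group, config$sex, seed = config$seed)$recordings
  }
  features <- extract_features(recordings, config)

  sel <- list(); cv <- list()
  for (nm in comparison_names()) {
    cmp <- comparison(nm, sex = config$sex)
    s <- suppressWarnings(screen_features(features, cmp,
                                          alpha = config$alpha))
    sel[[nm]] <- s
    use <- if (length(s$selected) > 0) s$selected else all_feature_names()
    cv[[nm]] <- run_cv(features, use, cmp, config$cv)
  }

  out <- structure(list(features = features, selection = sel, cv = cv,
                        config = config),
                   class = "bv_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

# Serialize a pipeline run: CSVs shaped like the clinical report tables plus
# a manifest holding every knob needed to reproduce the numbers.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  for (nm in names(run$selection))
    utils::write.csv(run$selection[[nm]]$table,
                     file.path(dir, paste0("selection_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(run$cv)) {
    rep <- run$cv[[nm]]
    m <- cbind(model = rownames(rep$metrics), round(rep$metrics, 1))
    utils::write.csv(m, file.path(dir, paste0("cv_", nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- run$config
  cfg$cv <- unclass(cfg$cv)
  manifest <- list(package = "bulbarvoice",
                   version = as.character(utils::packageVersion("bulbarvoice")),
                   config = unclass(cfg),
                   n_recordings = nrow(run$features),
                   selected = lapply(run$selection, `[[`, "selected"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}

#' @export
print.bv_run <- function(x, ...) {
  cat(sprintf("<bv_run> %d recordings, %d features\n", nrow(x$features),
              length(all_feature_names())))
  for (nm in names(x$cv)) {
    cat(sprintf("\n%s: %d features selected\n", nm,
                length(x$selection[[nm]]$selected)))
    print(round(x$cv[[nm]]$metrics, 1))
  }
  invisible(x)
}
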