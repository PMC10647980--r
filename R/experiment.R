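#' Configuration of a comparison study
#'
#' Declares the full desk-scale protocol: phantom data sizes, backbone,
#' task settings (append `"_aug"` for online rotation augmentation), training
#' hyper-parameters and seeds. Training and validation sets are generated
#' without rotation (the supine-position population); the 2D test set is
#' rotated within the phantom's rotation range; test volumes get one modest
#' whole-case angle each, drawn from `volume_angle_range` with random sign,
#' mimicking genuinely rotated patients.
#'
#' The defaults are the desk-scale study: 64x64 phantoms, 200 training and 50
#' validation slices, 300 rotated test slices, 5 test volumes of 16 slices,
#' depth-3 backbone with 8 base filters, 60 epochs, 3 seeds. The full-scale
#' reference settings (learning rate 1e-3, batch size 8, 3000 epochs on
#' 256x512 slices) are recorded in [reference_scale()]; learning rate and
#' batch size are kept at the reference values.
#'
#' @param phantom a [phantom_config()]; its `seed` fixes the generated data.
#' @param backbone a [backbone_config()].
#' @param settings character vector from `"STL"`, `"SCOS"`, `"TASKS1"`,
#'   `"TASKS2"`, and their `"_aug"` variants. `"STL"` trains one network per
#'   organ (three in total).
#' @param n_train,n_val,n_test_2d,n_test_volumes,volume_slices data sizes.
#' @param epochs,batch_size,learning_rate training hyper-parameters.
#' @param seeds integer training seeds (weight init, shuffling,
#'   augmentation); the phantom data are shared across seeds.
#' @param augment_range rotation interval (degrees) for `"_aug"` settings.
#' @param volume_angle_range magnitude interval (degrees) for the whole-case
#'   rotation of test volumes.
#' @param threshold binarisation threshold for evaluation.
#' @param log_val_loss also log the per-epoch validation loss during each
#'   training run (validation Dice is always evaluated after training;
#'   per-epoch validation-loss curves roughly double the forward passes per
#'   epoch, so they are off by default in the orchestrated study).
#' @param window intensity [window_spec()].
#' @return object of class `"experiment_config"`.
#' @export
experiment_config <- function(phantom = phantom_config(seed = 20230719L),
                              backbone = backbone_config(),
                              settings = c("STL", "SCOS", "TASKS1", "TASKS2",
                                           "STL_aug", "SCOS_aug"),
                              n_train = 200L, n_val = 50L, n_test_2d = 300L,
                              n_test_volumes = 5L, volume_slices = 16L,
                              epochs = 60L, batch_size = 8L,
                              learning_rate = 1e-3, seeds = c(1L, 2L, 3L),
                              augment_range = c(-30, 30),
                              volume_angle_range = c(1.5, 9.34),
                              threshold = 0.5, log_val_loss = FALSE,
                              window = window_spec()) {
  known <- c(SETTINGS_STUDY, paste0(SETTINGS_STUDY, "_aug"))
  if (!all(settings %in% known))
    stop("unknown setting(s): ",
         paste(setdiff(settings, known), collapse = ", "))
  if (is.null(phantom$seed))
    stop("the study phantom config needs a seed for reproducible data")
  structure(list(phantom = phantom, backbone = backbone, settings = settings,
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test_2d = as.integer(n_test_2d),
                 n_test_volumes = as.integer(n_test_volumes),
                 volume_slices = as.integer(volume_slices),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seeds = as.integer(seeds),
                 augment_range = augment_range,
                 volume_angle_range = volume_angle_range,
                 threshold = threshold, log_val_loss = log_val_loss,
                 window = window),
            class = "experiment_config")
}

SETTINGS_STUDY <- c("STL", "SCOS", "TASKS1", "TASKS2")

#' Full-scale reference hyper-parameters
#'
#' The defaults-of-record for the original clinical-scale experiment:
#' 256x512 slices, depth-5 backbone with 32 base filters, Adam with learning
#' rate 1e-3, batch size 8, 3000 epochs. The desk-scale study keeps the
#' optimiser settings and scales the rest down.
#'
#' @return named list.
#' @export
reference_scale <- function() {
  list(image_size = c(256L, 512L), depth = 5L, base_filters = 32L,
       learning_rate = 1e-3, batch_size = 8L, epochs = 3000L)
}

# one setting entry -> list of scosnet fits (one per organ for STL)
fit_setting <- function(name, train, val, config, seed, verbose) {
  augment <- endsWith(name, "_aug")
  base <- sub("_aug$", "", name)
  one <- function(setting_name) {
    if (verbose)
      cat(sprintf("  training %s (%s), seed %d ...\n", name, setting_name,
                  seed))
    scosnet(train, setting_name, config$backbone, epochs = config$epochs,
            batch_size = config$batch_size,
            learning_rate = config$learning_rate, augment = augment,
            augment_range = config$augment_range,
            val_data = if (isTRUE(config$log_val_loss)) val else NULL,
            seed = seed, window = config$window)
  }
  if (base == "STL") {
    fits <- lapply(paste0("STL_", ORGANS), one)
    names(fits) <- ORGANS
    fits
  } else {
    list(joint = one(base))
  }
}

# per-case organ probability masks for a list of slices
predict_organs <- function(fits, slices, threshold) {
  n <- length(slices)
  per_organ <- list()
  if (!is.null(fits$joint)) {
    pr <- predict(fits$joint, slices)
    for (org in ORGANS) per_organ[[org]] <- pr[[org]]
  } else {
    for (org in ORGANS) per_organ[[org]] <- predict(fits[[org]], slices)[[org]]
  }
  lapply(seq_len(n), function(i)
    lapply(per_organ, function(a) binarize(a[, , i], threshold)))
}

slices_truth <- function(slices) {
  lapply(slices, function(s) s$masks[ORGANS])
}

volume_truth <- function(vol) {
  out <- lapply(ORGANS, function(org) volume_mask_array(vol, org))
  names(out) <- ORGANS
  out
}

#' Run the full comparison study
#'
#' Generates the phantom data (shared across settings and seeds), trains every
#' configured setting for every seed, and evaluates each on (i) the unrotated
#' validation slices, (ii) the rotated 2D test slices without post-processing,
#' and (iii) the rotated test volumes in 3D with largest-connected-component
#' post-processing. No rotated sample ever enters a non-augmented training
#' stream (asserted internally).
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return object of class `"scos_study"`: list with
#'   \describe{
#'     \item{records}{per-case per-organ metric rows with `setting`, `seed`,
#'       `mode` (`"val"`, `"2d"`, `"3d"`).}
#'     \item{summary}{quartile summaries per (setting, seed, mode, organ,
#'       metric) including `n_inf`.}
#'     \item{fits}{the fitted networks, indexed `"<setting>/seed<k>"`.}
#'     \item{config, volume_angles}{provenance.}
#'   }
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ph <- config$phantom
  with_seed_offset <- function(off) {
    p <- ph; p$seed <- ph$seed + off; p
  }
  if (verbose) cat("generating phantom data ...\n")
  train <- generate_dataset(with_seed_offset(0L), config$n_train,
                            rotated = FALSE)
  val <- generate_dataset(with_seed_offset(1000L), config$n_val,
                          rotated = FALSE)
  test2d <- generate_dataset(with_seed_offset(2000L), config$n_test_2d,
                             rotated = TRUE)
  set.seed(ph$seed + 4000L)
  vol_angles <- sample(c(-1, 1), config$n_test_volumes, replace = TRUE) *
    runif(config$n_test_volumes, config$volume_angle_range[1],
          config$volume_angle_range[2])
  volumes <- lapply(seq_len(config$n_test_volumes), function(v)
    generate_volume(with_seed_offset(3000L + v), config$volume_slices,
                    vol_angles[v], case_id = sprintf("vol%04d", v)))
  # protocol purity: the training stream is strictly unrotated
  stopifnot(all(vapply(train, `[[`, 0, "angle_deg") == 0),
            all(vapply(val, `[[`, 0, "angle_deg") == 0))

  truth_val <- slices_truth(val)
  truth_2d <- slices_truth(test2d)
  truth_3d <- lapply(volumes, volume_truth)
  vol_spacing <- volumes[[1]]$spacing

  records <- list()
  fits_all <- list()
  for (seed in config$seeds) {
    for (setting in config$settings) {
      fits <- fit_setting(setting, train, val, config, seed, verbose)
      fits_all[[sprintf("%s/seed%d", setting, seed)]] <- fits
      tag <- function(df, mode) {
        if (NROW(df) == 0) return(NULL)
        df$setting <- setting; df$seed <- seed; df$mode <- mode
        df
      }
      pv <- predict_organs(fits, val, config$threshold)
      records[[length(records) + 1]] <-
        tag(evaluate_masks(pv, truth_val, "2d", postprocess = FALSE,
                           case_ids = vapply(val, `[[`, "", "case_id")),
            "val")
      p2 <- predict_organs(fits, test2d, config$threshold)
      records[[length(records) + 1]] <-
        tag(evaluate_masks(p2, truth_2d, "2d", postprocess = FALSE,
                           case_ids = vapply(test2d, `[[`, "", "case_id")),
            "2d")
      p3 <- lapply(volumes, function(vol) {
        pm <- predict_organs(fits, vol$slices, config$threshold)
        out <- lapply(ORGANS, function(org)
          simplify2array(lapply(pm, `[[`, org)))
        names(out) <- ORGANS
        out
      })
      records[[length(records) + 1]] <-
        tag(evaluate_masks(p3, truth_3d, "3d", spacing = vol_spacing,
                           postprocess = TRUE,
                           case_ids = vapply(volumes, function(v)
                             v$slices[[1]]$case_id, "")),
            "3d")
      if (verbose) {
        last <- records[[length(records) - 1]]
        cat(sprintf("  %s seed %d: rotated-2D median dice %s\n", setting,
                    seed,
                    paste(sprintf("%s=%.3f", ORGANS, vapply(ORGANS,
                      function(o) median(last$dice[last$organ == o]), 0)),
                      collapse = " ")))
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  summ <- list()
  for (setting in unique(records$setting))
    for (seed in unique(records$seed))
      for (mode in unique(records$mode)) {
        sub <- records[records$setting == setting & records$seed == seed &
                         records$mode == mode, ]
        if (NROW(sub) == 0) next
        s <- summarize_records(sub)
        s$setting <- setting; s$seed <- seed; s$mode <- mode
        summ[[length(summ) + 1]] <- s
      }
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL

  structure(list(records = records, summary = summ, fits = fits_all,
                 config = config, volume_angles = vol_angles),
            class = "scos_study")
}

#' @export
print.scos_study <- function(x, ...) {
  cat(sprintf("<scos_study: settings %s; seeds %s; %d metric records>\n",
              paste(x$config$settings, collapse = ", "),
              paste(x$config$seeds, collapse = ", "), nrow(x$records)))
  cat("\nRotated 2D test, median Dice and N(inf) over all seeds:\n")
  r2 <- x$records[x$records$mode == "2d", ]
  for (setting in unique(r2$setting)) {
    sub <- r2[r2$setting == setting, ]
    meds <- vapply(ORGANS, function(o) median(sub$dice[sub$organ == o]), 0)
    cat(sprintf("  %-9s %s  N(inf)=%d\n", setting,
                paste(sprintf("%s %.3f", ORGANS, meds), collapse = "  "),
                n_inf(sub)))
  }
  invisible(x)
}

#' Per-case Dice differences between two settings
#'
#' The paired per-case, per-organ difference `Dice(a) - Dice(b)` on identical
#' cases (the data behind a difference bar chart). Differences are
#' antisymmetric in the two settings and their mean equals the difference of
#' mean Dice.
#'
#' @param study a [run_study()] result.
#' @param setting_a,setting_b setting names present in the study.
#' @param mode `"2d"`, `"3d"` or `"val"`.
#' @param seed restrict to one training seed (default: all, paired within
#'   seed).
#' @return data frame `seed`, `case_id`, `organ`, `dice_a`, `dice_b`, `diff`,
#'   ordered by case id within seed.
#' @export
dice_difference <- function(study, setting_a, setting_b, mode = "2d",
                            seed = NULL) {
  r <- study$records[study$records$mode == mode, ]
  if (!is.null(seed)) r <- r[r$seed %in% seed, ]
  a <- r[r$setting == setting_a, c("seed", "case_id", "organ", "dice")]
  b <- r[r$setting == setting_b, c("seed", "case_id", "organ", "dice")]
  if (NROW(a) == 0 || NROW(b) == 0)
    stop("setting not present in the study records")
  m <- merge(a, b, by = c("seed", "case_id", "organ"),
             suffixes = c("_a", "_b"))
  if (NROW(m) != NROW(a) || NROW(m) != NROW(b))
    stop("case sets differ between the two settings")
  m$diff <- m$dice_a - m$dice_b
  m <- m[order(m$seed, m$case_id, m$organ), ]
  rownames(m) <- NULL
  m
}

#' Median of a metric for one setting/organ/mode slice of a study
#'
#' Convenience accessor used in reports: medians are over finite values, with
#' infinities counted separately via [n_inf()].
#'
#' @param study a [run_study()] result.
#' @param setting,organ,mode,seed filters (`NULL` = no filter).
#' @param metric one of `"dice"`, `"max_hd"`, `"hd95"`, `"asd"`.
#' @return scalar median.
#' @export
study_median <- function(study, setting, organ, mode = "2d", seed = NULL,
                         metric = "dice") {
  r <- study$records
  keep <- r$setting == setting & r$organ == organ & r$mode == mode
  if (!is.null(seed)) keep <- keep & r$seed %in% seed
  v <- r[[metric]][keep]
  median(v[is.finite(v)])
}
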