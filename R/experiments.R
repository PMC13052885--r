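# Experiment designs and runners. A design enumerates the condition grid of
# one experiment; the runner builds every stimulus through the transforms
# module (with a recorded seed, so any row can be regenerated exactly) and
# records restricted predictions for each classifier.

#' Experiment condition grids
#'
#' `design_exp1`: point-density proportions crossed with object orientation
#' (upright/inverted). The printed grid is 7 densities x 2 orientations over
#' 7 test instances x 10 categories (490 stimuli per orientation, 980 in
#' total for model testing).
#' `design_exp2`: voxel "Lego" deformation levels, including voxel size 0
#' (the undeformed cloud) alongside 0.01, 0.05, 0.1, 0.2.
#'
#' @param densities density proportions in (0, 1].
#' @param orientations subset of c("upright", "inverted").
#' @param voxel_sizes voxel edge lengths (0 = identity).
#' @param categories category subset used for restricted prediction.
#' @param seed base seed for stimulus generation.
#' @return An `experiment_design`.
#' @export
design_exp1 <- function(densities = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0),
                        orientations = c("upright", "inverted"),
                        categories = experiment_categories(), seed = 1L) {
  conditions <- expand.grid(density = densities, orientation = orientations,
                            stringsAsFactors = FALSE)
  structure(list(experiment = "exp1", conditions = conditions,
                 categories = categories, seed = as.integer(seed)),
            class = "experiment_design")
}

#' @rdname design_exp1
#' @export
design_exp2 <- function(voxel_sizes = c(0, 0.01, 0.05, 0.1, 0.2),
                        categories = experiment_categories(), seed = 1L) {
  structure(list(experiment = "exp2",
                 conditions = data.frame(voxel_size = voxel_sizes),
                 categories = categories, seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s: %d conditions x %d categories\n",
              x$experiment, nrow(x$conditions), length(x$categories)))
  invisible(x)
}

#' Per-participant Lego-experiment design
#'
#' Enumerates one participant's trial list: from each of the ten categories,
#' four object instances are drawn at random and each is randomly assigned
#' one of the four voxel sizes, giving 40 stimuli per participant.
#'
#' @param seed RNG seed for the draw.
#' @param voxel_sizes the four deformation levels.
#' @param categories the ten experiment categories.
#' @param n_instances_per_cat available instances per category to draw from.
#' @return data.frame with one row per trial (category, instance index,
#'   voxel size).
#' @export
design_exp2_participant <- function(seed,
                                    voxel_sizes = c(0.01, 0.05, 0.1, 0.2),
                                    categories = experiment_categories(),
                                    n_instances_per_cat = 7L) {
  n_draw <- length(voxel_sizes)
  stopifnot(n_instances_per_cat >= n_draw)
  with_seed(seed, {
    rows <- lapply(categories, function(cat) {
      inst <- sample.int(n_instances_per_cat, n_draw)
      data.frame(category = cat, instance_index = inst,
                 voxel_size = sample(voxel_sizes), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Run an experiment over a set of classifiers
#'
#' For every (classifier, condition, test instance) triple, builds the
#' stimulus from the stored cloud via the transforms module with a recorded
#' seed, predicts within the design's category subset, and returns a flat
#' predictions table. Every row carries enough provenance (instance id,
#' condition parameters, seed) to regenerate its stimulus exactly.
#'
#' @param classifiers named list of `point_classifier`s.
#' @param design an `experiment_design` (exp1 or exp2).
#' @param dataset a `shape_dataset` whose test split provides the base
#'   objects.
#' @return data.frame with columns model, condition parameters, instance_id,
#'   true, predicted, stim_seed.
#' @export
run_experiment <- function(classifiers, design, dataset) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(names(classifiers)) || any(!nzchar(names(classifiers)))) {
    stop("`classifiers` must be a named list", call. = FALSE)
  }
  test <- dataset_split(dataset, "test")
  test <- test[vapply(test, function(pc)
    pc$category %in% design$categories, logical(1))]
  if (!length(test)) stop("no test instances for the design categories",
                          call. = FALSE)
  out <- list()
  for (mname in names(classifiers)) {
    model <- classifiers[[mname]]
    for (ci in seq_len(nrow(design$conditions))) {
      cond <- design$conditions[ci, , drop = FALSE]
      for (ii in seq_along(test)) {
        pc <- test[[ii]]
        sseed <- derive_seed(design$seed, ci, ii)
        stim <- .build_stimulus(pc, design$experiment, cond, sseed)
        pred <- restrict_predict(model, stim, design$categories)
        out[[length(out) + 1L]] <- cbind(
          data.frame(model = mname, stringsAsFactors = FALSE),
          cond,
          data.frame(instance_id = pc$instance_id, true = pc$category,
                     predicted = pred, stim_seed = sseed,
                     stringsAsFactors = FALSE))
      }
    }
  }
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  rows
}

.build_stimulus <- function(pc, experiment, cond, sseed) {
  if (experiment == "exp1") {
    stim <- downsample_density(pc, cond$density, seed = sseed)
    if (cond$orientation == "inverted") stim <- invert(stim)
    stim
  } else if (experiment == "exp2") {
    if (cond$voxel_size == 0) pc else
      voxelize_lego(pc, cond$voxel_size, seed = sseed)
  } else {
    stop("unsupported experiment: ", experiment, call. = FALSE)
  }
}

#' Model-agreement filtering of part-scrambled stimuli
#'
#' Reproduces the scramble selection rule: a scrambled cloud is kept only if
#' the classifier assigns it the same (restricted) label as the original,
#' unscrambled cloud. For each original, scrambles are regenerated with
#' fresh seeds until one is accepted or `retry_cap` attempts are exhausted;
#' `quota_per_cat` originals per category are processed. Originals are
#' subdivided ([subdivide_large_parts()]) before scrambling.
#'
#' @param classifier a `point_classifier`.
#' @param originals list of part-labelled `point_cloud`s (>= quota per
#'   category).
#' @param config a `scramble_config`; its seed drives all draws.
#' @param category_subset restricted-prediction categories.
#' @param quota_per_cat accepted scrambles required per category.
#' @param retry_cap maximum scramble attempts per original.
#' @return list with `originals` (the clouds used), `scrambles` (accepted
#'   `stimulus_record`s, one per original) and `records` (a data.frame of
#'   instance, category, attempts, accepted seed).
#' @export
filter_scrambles <- function(classifier, originals, config = scramble_config(),
                             category_subset = scramble_categories(),
                             quota_per_cat = 10L, retry_cap = 200L) {
  cats <- vapply(originals, function(pc) pc$category, character(1))
  use_cats <- intersect(category_subset, unique(cats))
  chosen <- list()
  for (cat in use_cats) {
    pool <- which(cats == cat)
    if (length(pool) < quota_per_cat) {
      stop(sprintf("category %s has %d originals but quota is %d", cat,
                   length(pool), quota_per_cat), call. = FALSE)
    }
    chosen[[cat]] <- pool[seq_len(quota_per_cat)]
  }
  sel <- unlist(chosen, use.names = FALSE)
  kept_orig <- list(); kept_scr <- list(); recs <- list()
  failed <- character(0)
  for (oi in seq_along(sel)) {
    pc <- originals[[sel[oi]]]
    sub <- subdivide_large_parts(pc, config)
    base_pred <- restrict_predict(classifier, pc, category_subset)
    accepted <- NULL; attempts <- 0L
    for (a in seq_len(retry_cap)) {
      attempts <- a
      cfg <- config
      cfg$seed <- derive_seed(config$seed, oi, a)
      s <- scramble_parts(sub, cfg)
      if (identical(restrict_predict(classifier, s, category_subset),
                    base_pred)) {
        accepted <- s
        break
      }
    }
    if (is.null(accepted)) {
      failed <- c(failed, pc$category)
      next
    }
    kept_orig[[length(kept_orig) + 1L]] <- pc
    kept_scr[[length(kept_scr) + 1L]] <- accepted
    recs[[length(recs) + 1L]] <- data.frame(
      instance_id = pc$instance_id, category = pc$category,
      attempts = attempts, accepted_seed = accepted$provenance$seed,
      stringsAsFactors = FALSE)
  }
  if (length(failed)) {
    stop("scramble quota unreachable within retry cap for categories: ",
         paste(sort(unique(failed)), collapse = ", "), call. = FALSE)
  }
  list(originals = kept_orig, scrambles = kept_scr,
       records = do.call(rbind, recs))
}

#' Build the full part-scrambling stimulus set
#'
#' For each source classifier, selects `quota_per_cat` originals per
#' category and one model-agreement-filtered scramble per original
#' ([filter_scrambles()]). With two source models, 10 per category, and the
#' five scramble categories this yields 2 x 5 x 10 x 2 = 200 stimuli
#' (original + scrambled for each source model).
#'
#' @param classifiers named list of source `point_classifier`s.
#' @param dataset a `shape_dataset`; its test split provides part-labelled
#'   originals.
#' @param config a `scramble_config`.
#' @param categories scramble categories.
#' @param quota_per_cat originals per category per source model.
#' @param retry_cap per-original scramble attempt cap.
#' @return list with `stimuli` (data.frame: stim_id, source_model,
#'   condition, instance_id, category) and `clouds` (named list of
#'   `point_cloud`s keyed by stim_id).
#' @export
build_exp3_stimuli <- function(classifiers, dataset,
                               config = scramble_config(),
                               categories = scramble_categories(),
                               quota_per_cat = 10L, retry_cap = 200L) {
  test <- dataset_split(dataset, "test")
  test <- test[vapply(test, function(pc) pc$category %in% categories,
                      logical(1))]
  rows <- list(); clouds <- list()
  for (mname in names(classifiers)) {
    fs <- filter_scrambles(classifiers[[mname]], test, config, categories,
                           quota_per_cat, retry_cap)
    for (i in seq_along(fs$originals)) {
      for (cond in c("intact", "scrambled")) {
        pc <- if (cond == "intact") fs$originals[[i]] else fs$scrambles[[i]]
        sid <- sprintf("%s_%s_%s", mname, cond, fs$records$instance_id[i])
        clouds[[sid]] <- pc
        rows[[length(rows) + 1L]] <- data.frame(
          stim_id = sid, source_model = mname, condition = cond,
          instance_id = fs$records$instance_id[i],
          category = fs$records$category[i], stringsAsFactors = FALSE)
      }
    }
  }
  list(stimuli = do.call(rbind, rows), clouds = clouds)
}

#' Predict a prepared stimulus set with each classifier
#'
#' @param classifiers named list of `point_classifier`s.
#' @param stimulus_set result of [build_exp3_stimuli()] (or any list with
#'   `stimuli` and `clouds`).
#' @param category_subset restricted-prediction categories.
#' @return the `stimuli` data.frame with one block per model: columns model,
#'   true, predicted appended.
#' @export
predict_stimuli <- function(classifiers, stimulus_set,
                            category_subset = scramble_categories()) {
  out <- list()
  for (mname in names(classifiers)) {
    df <- stimulus_set$stimuli
    df$model <- mname
    df$true <- df$category
    df$predicted <- vapply(df$stim_id, function(sid)
      restrict_predict(classifiers[[mname]], stimulus_set$clouds[[sid]],
                       category_subset), character(1))
    out[[mname]] <- df
  }
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  rows
}
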