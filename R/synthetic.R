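#' Generate one part-annotated point-cloud object from a template
#'
#' Size parameters are jittered uniformly within +/- 20% of their template
#' defaults (driven by `instance_seed`, giving within-category instance
#' variation), primitives are rebuilt, and `n_points` points are sampled
#' area-uniformly over the union of primitive surfaces: each point first
#' selects a primitive with probability proportional to its analytic surface
#' area, then is placed uniformly on that surface. Part labels are inherited
#' from the sampled primitive. The cloud is unit-sphere normalized. The
#' result is deterministic given `(template, instance_seed, n_points)`.
#'
#' @param template a `shape_template`.
#' @param instance_seed integer seed identifying the instance.
#' @param n_points number of surface points (default 1024).
#' @param jitter relative half-range of the size jitter (default 0.2).
#' @return A `point_cloud` with `part_labels`.
#' @export
generate_object <- function(template, instance_seed, n_points = 1024L,
                            jitter = 0.2) {
  stopifnot(inherits(template, "shape_template"), n_points >= 1)
  with_seed(instance_seed, {
    pars <- as.list(template$defaults *
                      runif(length(template$defaults), 1 - jitter, 1 + jitter))
    names(pars) <- names(template$defaults)
    built <- template$builder(pars)
    .validate_built(built, template$category_name)
    areas <- vapply(built$primitives, function(p) p$area, numeric(1))
    if (sum(areas) <= 0) {
      stop("degenerate template: total surface area is zero", call. = FALSE)
    }
    prim_idx <- sample.int(length(areas), n_points, replace = TRUE,
                           prob = areas)
    coords <- matrix(0, n_points, 3)
    for (i in seq_along(areas)) {
      sel <- which(prim_idx == i)
      if (length(sel)) {
        coords[sel, ] <- .prim_sample(built$primitives[[i]], length(sel))
      }
    }
    pc <- point_cloud(coords,
                      part_labels = as.integer(built$part_of[prim_idx]),
                      category = template$category_name,
                      instance_id = sprintf("%s_s%d", template$category_name,
                                            as.integer(instance_seed)))
    normalize_unit_sphere(pc)
  })
}

#' Generate a labelled train/test dataset of synthetic objects
#'
#' Instance seeds are derived deterministically from `seed` and are disjoint
#' between the train and test splits. The manifest lists every instance with
#' its category, split, seed, and (when `out_dir` is given) the paths of its
#' PLY cloud and `.seg` part-label files.
#'
#' @param templates list of `shape_template` objects (unique categories).
#' @param n_train_per_cat,n_test_per_cat instances per category and split.
#' @param seed base RNG seed.
#' @param n_points points per cloud.
#' @param out_dir optional directory; when given, clouds, labels and a
#'   `manifest.json` are written there.
#' @return A `shape_dataset`: list with `manifest` (data.frame), `clouds`
#'   (named list of `point_cloud`), and `config`.
#' @export
generate_dataset <- function(templates, n_train_per_cat, n_test_per_cat,
                             seed, n_points = 1024L, out_dir = NULL) {
  stopifnot(n_train_per_cat >= 1 || n_test_per_cat >= 1)
  if (inherits(templates, "shape_template")) templates <- list(templates)
  cats <- vapply(templates, function(t) t$category_name, character(1))
  if (anyDuplicated(cats)) {
    stop("duplicate category names: ",
         paste(unique(cats[duplicated(cats)]), collapse = ", "), call. = FALSE)
  }
  rows <- list()
  clouds <- list()
  for (ci in seq_along(templates)) {
    tpl <- templates[[ci]]
    n_tot <- n_train_per_cat + n_test_per_cat
    for (j in seq_len(n_tot)) {
      iseed <- derive_seed(seed, ci, j)
      split <- if (j <= n_train_per_cat) "train" else "test"
      id <- sprintf("%s_%03d", tpl$category_name, j)
      pc <- generate_object(tpl, iseed, n_points = n_points)
      pc$instance_id <- id
      clouds[[id]] <- pc
      rows[[length(rows) + 1L]] <- data.frame(
        instance_id = id, category = tpl$category_name, split = split,
        instance_seed = iseed,
        cloud_path = if (is.null(out_dir)) NA_character_ else
          file.path(out_dir, paste0(id, ".ply")),
        seg_path = if (is.null(out_dir)) NA_character_ else
          file.path(out_dir, paste0(id, ".seg")),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  config <- list(categories = unname(cats), n_train_per_cat = n_train_per_cat,
                 n_test_per_cat = n_test_per_cat, seed = as.integer(seed),
                 n_points = as.integer(n_points))
  ds <- structure(list(manifest = manifest, clouds = clouds, config = config),
                  class = "shape_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(clouds)) {
      write_ply(clouds[[id]], file.path(out_dir, paste0(id, ".ply")))
      write_seg_labels(clouds[[id]]$part_labels,
                       file.path(out_dir, paste0(id, ".seg")))
    }
    write_manifest(ds, file.path(out_dir, "manifest.json"))
  }
  ds
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf("<shape_dataset> %d instances, %d categories (%d train / %d test per category)\n",
              nrow(x$manifest), length(x$config$categories),
              x$config$n_train_per_cat, x$config$n_test_per_cat))
  invisible(x)
}

#' Subset a dataset by split
#' @param dataset a `shape_dataset`.
#' @param split "train" or "test".
#' @return list of `point_cloud`s in manifest order.
#' @export
dataset_split <- function(dataset, split = c("train", "test")) {
  split <- match.arg(split)
  ids <- dataset$manifest$instance_id[dataset$manifest$split == split]
  dataset$clouds[ids]
}
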