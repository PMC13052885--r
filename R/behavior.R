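# Behavioural-comparison statistics: confusion matrices, off-diagonal
# confusion correlations, pooled accuracy-pattern correlations, and
# Steiger's test for two dependent correlations sharing one variable.

#' Confusion matrix from a predictions table
#'
#' Rows are true categories, columns predicted categories, in the supplied
#' category order.
#'
#' @param predictions data.frame with `true` and `predicted` columns.
#' @param categories ordered category roster; any label outside it is an
#'   error.
#' @return A `confusion_matrix`: integer C x C matrix with dimnames.
#' @export
confusion_from_predictions <- function(predictions, categories) {
  stopifnot(is.data.frame(predictions),
            all(c("true", "predicted") %in% names(predictions)))
  bad <- setdiff(unique(c(predictions$true, predictions$predicted)),
                 categories)
  if (length(bad)) {
    stop("labels outside the category roster: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tt <- factor(predictions$true, levels = categories)
  pp <- factor(predictions$predicted, levels = categories)
  cm <- unclass(table(true = tt, predicted = pp))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Pearson correlation of off-diagonal confusion structure
#'
#' Each matrix is row-normalised to response proportions (so unequal
#' per-category trial counts between observers do not confound the
#' comparison; set `normalize = FALSE` for raw counts), the diagonal
#' (correct responses) is removed, the remaining C(C-1) cells are flattened
#' in row-major order, and a Pearson correlation is computed with a
#' two-sided p from the t transform on C(C-1) - 2 degrees of freedom.
#'
#' @param cm_a,cm_b confusion matrices with identical category orderings
#'   (C >= 3).
#' @param normalize row-normalise to proportions before comparing.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
offdiag_correlation <- function(cm_a, cm_b, normalize = TRUE) {
  cm_a <- as.matrix(cm_a); cm_b <- as.matrix(cm_b)
  if (!identical(dim(cm_a), dim(cm_b)) ||
      !identical(rownames(cm_a), rownames(cm_b))) {
    stop("confusion matrices must share dimensions and category order",
         call. = FALSE)
  }
  C <- nrow(cm_a)
  if (C < 3) stop("at least 3 categories are required", call. = FALSE)
  va <- .offdiag_vec(cm_a, normalize)
  vb <- .offdiag_vec(cm_b, normalize)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("off-diagonal correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(va, vb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(va))
}

.offdiag_vec <- function(cm, normalize) {
  m <- cm
  if (normalize) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  off <- t(m) # row-major flatten
  off[as.vector(t(diag(nrow(m)) == 0))]
}

#' Accuracy profile over experimental conditions
#'
#' An ordered map from condition id to mean classification accuracy.
#'
#' @param condition character vector of unique condition ids.
#' @param accuracy accuracies in 0 to 1.
#' @param n trial counts (optional).
#' @return An `accuracy_profile` data.frame.
#' @export
accuracy_profile <- function(condition, accuracy, n = NA_integer_) {
  condition <- as.character(condition)
  if (anyDuplicated(condition)) {
    stop("condition ids must be unique", call. = FALSE)
  }
  if (any(accuracy < 0 | accuracy > 1)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(condition = condition, accuracy = accuracy, n = n,
                       stringsAsFactors = FALSE),
            class = c("accuracy_profile", "data.frame"))
}

#' Accuracy profile from a predictions table
#'
#' @param predictions data.frame with `true`, `predicted` and the columns
#'   named in `condition_cols`.
#' @param condition_cols column names defining a condition.
#' @return An `accuracy_profile` (conditions in first-appearance order).
#' @export
accuracy_from_predictions <- function(predictions, condition_cols) {
  stopifnot(all(condition_cols %in% names(predictions)))
  key <- do.call(paste, c(predictions[condition_cols], sep = "|"))
  keys <- unique(key)
  acc <- vapply(keys, function(kk) {
    sel <- key == kk
    mean(predictions$predicted[sel] == predictions$true[sel])
  }, numeric(1))
  nn <- vapply(keys, function(kk) sum(key == kk), numeric(1))
  accuracy_profile(keys, unname(acc), as.integer(nn))
}

#' Pearson correlation between two accuracy profiles
#'
#' Profiles must list the same conditions in the same order (n >= 3).
#'
#' @param profile_a,profile_b `accuracy_profile`s.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
accuracy_pattern_correlation <- function(profile_a, profile_b) {
  if (!identical(profile_a$condition, profile_b$condition)) {
    stop("profiles must share the same condition list and order",
         call. = FALSE)
  }
  n <- nrow(profile_a)
  if (n < 3) stop("at least 3 conditions are required", call. = FALSE)
  if (stats::sd(profile_a$accuracy) == 0 ||
      stats::sd(profile_b$accuracy) == 0) {
    stop("accuracy-pattern correlation undefined: zero variance",
         call. = FALSE)
  }
  ct <- stats::cor.test(profile_a$accuracy, profile_b$accuracy,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = n)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Tests r1 = cor(X, Y1) against r2 = cor(X, Y2), where r12 = cor(Y1, Y2)
#' (here X is typically the human accuracy profile and Y1, Y2 two models).
#' Uses Steiger's (1980) Z on Fisher-transformed correlations with the
#' Pearson-Filon covariance term. The sign convention is z < 0 when
#' r1 < r2.
#'
#' @param r1,r2 the two dependent correlations (|r| < 1).
#' @param r12 the correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return list with `z` and two-sided `p`.
#' @export
compare_dependent_correlations <- function(r1, r2, r12, n) {
  for (r in c(r1, r2, r12)) {
    if (!is.finite(r) || abs(r) >= 1) {
      stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
    }
  }
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  # pooled-correlation covariance estimate between the Fisher z's
  rbar <- (r1 + r2) / 2
  psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' The pooled condition list for cross-experiment accuracy correlations
#'
#' Enumerates, in a fixed order, every condition entering the pooled
#' human-model accuracy-pattern correlation: the 14 density x orientation
#' conditions, the five voxel-deformation levels (including the intact
#' level 0), and the part-scrambling conditions (intact plus one scrambled
#' condition per source model).
#'
#' @param densities density proportions of the first experiment.
#' @param voxel_sizes voxel levels of the second experiment.
#' @param scramble_sources names of the scramble source models.
#' @return character vector of condition ids.
#' @export
pooled_condition_list <- function(densities = c(0.2, 0.3, 0.4, 0.5, 0.6,
                                                0.8, 1.0),
                                  voxel_sizes = c(0, 0.01, 0.05, 0.1, 0.2),
                                  scramble_sources = c("dgcnn",
                                                       "point_transformer")) {
  c(sprintf("density_%g_%s", rep(densities, times = 2),
            rep(c("upright", "inverted"), each = length(densities))),
    sprintf("lego_%g", voxel_sizes),
    "scramble_intact",
    sprintf("scramble_by_%s", scramble_sources))
}

#' Load an externally supplied human behavioural table
#'
#' Delimited text with a header. Two schemas are recognised:
#' an accuracy profile (`condition`, `accuracy`, optional `n`) and a
#' confusion matrix (`true` followed by one column per predicted category,
#' with one row per true category named in `true`). Anything else is an
#' error naming the offending columns.
#'
#' @param path file path.
#' @param sep field separator.
#' @return An `accuracy_profile` or `confusion_matrix`.
#' @export
load_human_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("condition", "accuracy") %in% names(df))) {
    extra <- setdiff(names(df), c("condition", "accuracy", "n"))
    if (length(extra)) {
      stop(path, ": unexpected columns in accuracy profile: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (any(df$accuracy < 0 | df$accuracy > 1)) {
      stop(path, ": accuracies outside [0, 1]", call. = FALSE)
    }
    return(accuracy_profile(df$condition, df$accuracy,
                            if ("n" %in% names(df)) df$n else NA_integer_))
  }
  if (names(df)[1] == "true") {
    cats <- names(df)[-1]
    if (!identical(sort(df$true), sort(cats))) {
      stop(path, ": confusion rows and columns must name the same categories",
           call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$true
    m <- m[cats, , drop = FALSE] # align row order to column order
    storage.mode(m) <- "integer"
    return(structure(m, class = c("confusion_matrix", class(m))))
  }
  stop(path, ": unrecognised schema; expected columns (condition, accuracy",
       "[, n]) or (true, <categories...>); found: ",
       paste(names(df), collapse = ", "), call. = FALSE)
}

#' @rdname load_human_table
#' @param x an `accuracy_profile` or `confusion_matrix`.
#' @export
write_human_table <- function(x, path, sep = ",") {
  if (inherits(x, "confusion_matrix")) {
    df <- data.frame(true = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
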