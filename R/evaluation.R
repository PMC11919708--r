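#' Area under the ROC curve (Mann-Whitney construction)
#'
#' The probability that a randomly chosen presence scores above a randomly
#' chosen (pseudo-)absence, with ties counting one half — computed from
#' ranks, so it is exact and invariant under any strictly increasing
#' transform of the scores.
#'
#' @param scores_presence scores at presence points.
#' @param scores_absence scores at absence points.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores_presence, scores_absence) {
  m <- length(scores_presence); n <- length(scores_absence)
  if (m == 0 || n == 0)
    stop_invalid("both score lists must be non-empty (m=%d, n=%d)", m, n)
  r <- rank(c(scores_presence, scores_absence), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Quality band for a mean AUC
#'
#' Bands: below 0.6 bad; 0.6-0.7 poor; 0.7-0.8 satisfactory; 0.8-0.9 good;
#' above 0.9 excellent.
#'
#' @param mean_auc numeric AUC.
#' @return character band label.
#' @export
quality_band <- function(mean_auc) {
  if (mean_auc < 0.6) "bad"
  else if (mean_auc < 0.7) "poor"
  else if (mean_auc < 0.8) "satisfactory"
  else if (mean_auc <= 0.9) "good"
  else "excellent"
}

# stratified fold assignment: fold sizes differ by at most one per class
stratified_folds <- function(labels, k, seed) {
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' k-fold cross-validated AUC
#'
#' Stratified random partition (presence/absence proportions preserved; fold
#' sizes within each class differ by at most one). For each fold the model
#' is fitted on the other k-1 folds and scored on the held-out fold.
#'
#' @param fit_function function taking a training table and returning a
#'   scoring function `function(newdata) -> scores`.
#' @param training_table presence/background table.
#' @param k number of folds (default 10).
#' @param seed integer seed for the partition.
#' @param model_kind label stored in the report ("maxent" or "dl").
#' @return object of class `eval_report` with `fold_aucs`, `mean_auc`,
#'   `quality_band`, `fold_assignment`, `seed`.
#' @export
crossval_auc <- function(fit_function, training_table, k = 10, seed = 1,
                         model_kind = "model") {
  cnt <- table_counts(training_table)
  if (any(cnt < k))
    stop_invalid("need at least k=%d rows of each label (m=%d, n=%d)", k,
                 cnt["m"], cnt["n"])
  fold <- stratified_folds(training_table$label, k, seed)
  fold_aucs <- numeric(k)
  for (f in seq_len(k)) {
    train <- training_table[fold != f, , drop = FALSE]
    test <- training_table[fold == f, , drop = FALSE]
    score <- fit_function(train)
    s <- score(test)
    fold_aucs[f] <- auc(s[test$label == 1L], s[test$label == 0L])
  }
  structure(
    list(month_id = training_table$month_id[1], model_kind = model_kind,
         fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
         quality_band = quality_band(mean(fold_aucs)),
         fold_assignment = fold, seed = seed),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s %s: mean AUC %.3f (%s), folds [%s]>\n",
              x$month_id, x$model_kind, x$mean_auc, x$quality_band,
              paste(sprintf("%.2f", x$fold_aucs), collapse = " ")))
  invisible(x)
}

#' Permutation importance of the covariates
#'
#' Shuffles one covariate column at a time (`n_repeats` shuffles, mean
#' effect) and records the drop in AUC relative to the unshuffled baseline.
#' Negative drops are floored at zero (a permutation that "helps" is
#' noise). Drops are normalized to percentages summing to 100; if every
#' drop is zero the importance is reported uniform with a warning.
#'
#' @param model_predict scoring function `function(newdata) -> scores`.
#' @param test_table table with covariate columns and `label` (ideally
#'   held-out data).
#' @param seed integer seed.
#' @param n_repeats permutations per covariate (default 10).
#' @return named numeric vector of percentages over the six covariates.
#' @export
permutation_importance <- function(model_predict, test_table, seed = 1,
                                   n_repeats = 10) {
  if (nrow(test_table) < 2)
    stop_invalid("need at least 2 rows for permutation importance")
  table_counts(test_table)
  is_p <- test_table$label == 1L
  s0 <- model_predict(test_table)
  base <- auc(s0[is_p], s0[!is_p])
  set.seed(derive_seed(seed, "perm-imp"))
  drops <- stats::setNames(numeric(length(COVARIATE_NAMES)), COVARIATE_NAMES)
  for (nm in COVARIATE_NAMES) {
    d <- 0
    for (r in seq_len(n_repeats)) {
      perm <- test_table
      perm[[nm]] <- sample(perm[[nm]])
      s <- model_predict(perm)
      d <- d + (base - auc(s[is_p], s[!is_p]))
    }
    drops[nm] <- max(0, d / n_repeats)
  }
  if (sum(drops) == 0) {
    warning("all permutation drops are zero; importance reported uniform",
            call. = FALSE)
    return(stats::setNames(rep(100 / length(drops), length(drops)),
                           names(drops)))
  }
  100 * drops / sum(drops)
}

#' Monthly AUC results grid
#'
#' Table-3-shaped container: one row per (year, model kind), one column per
#' calendar month, cells holding the month's mean AUC (NA where no model
#' was built).
#'
#' @param cells data.frame with columns `year`, `model_kind`, `month`
#'   (integer 1-12 or month name), `auc`.
#' @param months integer months spanned by the columns (default 3:10,
#'   March-October).
#' @return object of class `results_grid`: a matrix with rownames
#'   "year/model_kind" and month-name colnames.
#' @export
results_grid <- function(cells, months = 3:10) {
  if (!nrow(cells)) stop_invalid("empty results grid")
  mn <- cells$month
  if (is.character(mn)) mn <- match(mn, month.name)
  rows <- unique(cells[c("year", "model_kind")])
  g <- matrix(NA_real_, nrow(rows), length(months),
              dimnames = list(paste(rows$year, rows$model_kind, sep = "/"),
                              month.name[months]))
  for (i in seq_len(nrow(cells))) {
    rn <- paste(cells$year[i], cells$model_kind[i], sep = "/")
    g[rn, match(mn[i], months)] <- cells$auc[i]
  }
  structure(g, class = c("results_grid", "matrix"))
}

#' Summarize a results grid
#'
#' Per-row yearly averages (arithmetic mean over non-missing cells, rounded
#' to 3 decimals, round-half-even), counts of monthly AUCs strictly above
#' the threshold per model kind, the corresponding whole-number
#' percentages, and per-model overall averages.
#'
#' @param grid a `results_grid`, or any matrix with "year/model" rownames.
#' @param threshold AUC threshold for the counts (default 0.7, the
#'   satisfactory-model boundary).
#' @return list with `row_averages`, `counts_above`, `percent_above`,
#'   `model_averages`, `threshold`.
#' @export
summarize_grid <- function(grid, threshold = 0.7) {
  if (!length(grid) || all(is.na(grid))) stop_invalid("empty results grid")
  row_avg <- round(apply(grid, 1, mean, na.rm = TRUE), 3)
  kinds <- sub("^[^/]*/", "", rownames(grid))
  counts <- integer(0); pct <- integer(0); mavg <- numeric(0)
  for (kd in unique(kinds)) {
    cells <- grid[kinds == kd, , drop = FALSE]
    vals <- cells[!is.na(cells)]
    counts[kd] <- sum(vals > threshold)
    pct[kd] <- round(100 * counts[kd] / length(vals))
    mavg[kd] <- round(mean(vals), 3)
  }
  list(row_averages = row_avg, counts_above = counts, percent_above = pct,
       model_averages = mavg, threshold = threshold)
}
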