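#' Average the same calendar month's covariates across years
#'
#' Cell-wise nodata-aware arithmetic mean of the dynamic layers (a cell is
#' nodata only when it is nodata in every year); the static layers (depth,
#' slope, distance to shore) are constant by definition and passed through
#' from the first stack.
#'
#' @param stacks list of `env_stack` for the same calendar month across
#'   years, on identical grids.
#' @param month_id label for the averaged stack (default
#'   "avg-<first input>").
#' @return an `env_stack`.
#' @export
average_covariates <- function(stacks, month_id = NULL) {
  if (!length(stacks)) stop_invalid("need at least one stack to average")
  ref <- stacks[[1]]
  if (is.null(month_id)) month_id <- paste0("avg-", ref$month_id)
  layers <- list()
  for (nm in names(ref$layers)) {
    if (nm %in% STATIC_LAYERS) {
      layers[[nm]] <- ref$layers[[nm]]
    } else {
      layers[[nm]] <- mean_layer(lapply(stacks, function(s) s$layers[[nm]]))
    }
  }
  env_stack(month_id, layers)
}

projection_result <- function(month_id, model_kind, map, auc_vs_actual,
                              n_test_sightings, min_support = 5,
                              seed = NA_integer_) {
  structure(
    list(month_id = month_id, model_kind = model_kind, map = map,
         auc_vs_actual = auc_vs_actual,
         n_test_sightings = as.integer(n_test_sightings),
         low_support_flag = n_test_sightings < min_support, seed = seed),
    class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection %s %s: AUC %.3f on %d sightings%s>\n",
              x$month_id, x$model_kind, x$auc_vs_actual, x$n_test_sightings,
              if (x$low_support_flag) " [low support]" else ""))
  invisible(x)
}

#' Project with a maximum-entropy model trained on averaged conditions
#'
#' Implements the forward-projection protocol for the presence/background
#' model: pool the historical sightings and pseudo-absences of one calendar
#' month across years, read their covariates from the multi-year averaged
#' stack, fit a fresh model, predict over the target month's stack, and
#' score against the target month's actual sightings versus its own
#' effort-based pseudo-absences.
#'
#' @param history list with elements `presences` (list of data.frames per
#'   year), `absences` (likewise), `stacks` (list of `env_stack` per year).
#' @param target_stack the projection month's `env_stack`.
#' @param test_presences,test_absences the target month's points.
#' @param beta,knots_per_covariate engine settings.
#' @param min_support sightings below which the low-support flag is raised.
#' @return a `projection_result`.
#' @export
project_maxent <- function(history, target_stack, test_presences,
                           test_absences, beta = 1,
                           knots_per_covariate = 30, min_support = 5) {
  if (!length(history$stacks))
    stop_invalid("no historical years supplied for this calendar month")
  if (!length(history$presences) ||
      !sum(vapply(history$presences, nrow, integer(1))))
    stop_invalid("no historical sightings for this calendar month")
  avg <- average_covariates(history$stacks)
  tabs <- lapply(seq_along(history$presences), function(i)
    make_training_table(avg, history$presences[[i]], history$absences[[i]]))
  tt <- do.call(rbind, tabs)
  model <- fit_maxent(tt, beta = beta,
                      basis = build_hinge_basis(tt, knots_per_covariate))
  map <- predict_maxent(model, target_stack)
  test_tt <- make_training_table(target_stack, test_presences, test_absences)
  sc <- predict_maxent_points(model, test_tt)
  a <- auc(sc[test_tt$label == 1L], sc[test_tt$label == 0L])
  res <- projection_result(target_stack$month_id, "maxent", map, a,
                           nrow(test_presences), min_support)
  res$model <- model
  res
}

#' Project with the final continuously updated network
#'
#' No retraining: the last warm-started model from the training sequence is
#' applied to the target month's stack and scored against the actual
#' sightings versus the target month's pseudo-absences.
#'
#' @param final_model the trained `mlp_model` ending the monthly lineage.
#' @param target_stack the projection month's `env_stack`.
#' @param test_presences,test_absences the target month's points.
#' @param min_support sightings below which the low-support flag is raised.
#' @return a `projection_result`.
#' @export
project_dl <- function(final_model, target_stack, test_presences,
                       test_absences, min_support = 5) {
  if (is.null(final_model$standardization) || !length(final_model$provenance))
    stop("final model is untrained; run the monthly sequence first",
         call. = FALSE)
  map <- predict_mlp(final_model, target_stack)
  test_tt <- make_training_table(target_stack, test_presences, test_absences)
  sc <- predict_mlp_points(final_model, test_tt)
  a <- auc(sc[test_tt$label == 1L], sc[test_tt$label == 0L])
  projection_result(target_stack$month_id, "dl", map, a,
                    nrow(test_presences), min_support)
}

#' Study configuration
#'
#' All knobs of the synthetic end-to-end study in one validated object.
#' Defaults mirror the study system the package emulates: a small coastal
#' bay on a 500 m grid, months March-October, ~150 sightings and ~40
#' three-hour tours per month, and a true suitability driven dominantly by
#' sea-surface temperature with secondary depth structure.
#'
#' @param train_months character vector of "YYYY-MM" training months.
#' @param projection_months character vector of projection months (must be
#'   disjoint from `train_months`).
#' @param shape grid (rows, cols).
#' @param cell_size cell edge, meters.
#' @param seed master seed; every stage derives its own child seed.
#' @param n_presences sightings per month (recycled over months).
#' @param n_tours tours per month (recycled), or NULL to draw daily counts
#'   Poisson(1.43).
#' @param suitability_coefficients named per-covariate effects (per-SD, on
#'   the logit scale) of the true suitability.
#' @param intercept true-suitability intercept.
#' @param beta,knots_per_covariate maximum-entropy engine settings.
#' @param mlp an `mlp_config` for the network lineage.
#' @param k cross-validation folds.
#' @param bandwidth trackline-density kernel bandwidth, cells.
#' @param out_dir directory for report files (NULL = no files written).
#' @return object of class `study_config`.
#' @export
study_config <- function(train_months, projection_months = character(0),
                         shape = c(64, 64), cell_size = 500, seed = 1,
                         n_presences = 150, n_tours = 40,
                         suitability_coefficients = c(
                           sst = 3.5, chlorophyll_a = 0.8, salinity = 0,
                           depth = -1.2, slope = 0, dist_shore = 0),
                         intercept = -2.5, beta = 1,
                         knots_per_covariate = 10,
                         mlp = mlp_config(), k = 10, bandwidth = 2,
                         out_dir = NULL) {
  if (length(intersect(train_months, projection_months)))
    stop_invalid("projection months must be disjoint from training months")
  structure(
    list(train_months = train_months, projection_months = projection_months,
         shape = shape, cell_size = cell_size, seed = as.integer(seed),
         n_presences = n_presences, n_tours = n_tours,
         suitability_coefficients = suitability_coefficients,
         intercept = intercept, beta = beta,
         knots_per_covariate = knots_per_covariate, mlp = mlp, k = k,
         bandwidth = bandwidth, out_dir = out_dir),
    class = "study_config")
}

#' Simulate one month of the synthetic study world
#'
#' Dynamic covariate layers, the month's stack, the true suitability, tours
#' with effort, the trackline-density surface, presences, and
#' effort-proportional pseudo-absences.
#'
#' @param static output of [gen_static_layers()].
#' @param month_id "YYYY-MM".
#' @param config a `study_config`.
#' @param month_index position of the month in the study sequence (recycles
#'   vector-valued config entries).
#' @return list with `stack`, `truth`, `tours`, `density`, `presences`,
#'   `absences`, `effort`.
#' @export
simulate_month <- function(static, month_id, config, month_index = 1) {
  shape <- dim(static$depth$values)
  land <- static$land
  dyn <- lapply(stats::setNames(DYNAMIC_LAYERS, DYNAMIC_LAYERS), function(nm)
    gen_dynamic_layer(shape, config$cell_size, month_id, nm,
                      seed = config$seed, nodata_mask = land))
  stack <- env_stack(month_id, c(dyn, list(
    depth = static$depth, slope = static$slope,
    dist_shore = static$dist_shore)))
  truth <- make_true_suitability(stack, config$suitability_coefficients,
                                 config$intercept)
  # harbor on the coastline: westmost land cell of the middle row
  mid <- ceiling(shape[1] / 2)
  coast_col <- which(land[mid, ])[1]
  harbor <- cell_center(static$depth, mid, max(coast_col - 1, 1))
  n_tours <- if (is.null(config$n_tours)) NULL
             else rep_len(config$n_tours, month_index)[month_index]
  water <- mask_depth(static$depth)  # land carries no effort density
  tours <- simulate_tours(c(harbor), water, month_id,
                          n_tours = n_tours, seed = config$seed)
  dens <- trackline_density(tours$tracklines, water,
                            bandwidth = config$bandwidth)
  n_pres <- rep_len(config$n_presences, month_index)[month_index]
  presences <- sample_presences(truth, tours$tracklines, n_pres,
                                seed = config$seed,
                                bandwidth = config$bandwidth,
                                month_id = month_id)
  n_abs <- n_pseudo_absences(tours$effort)
  absences <- sample_absences(dens, n_abs, seed = config$seed,
                              month_id = month_id)
  list(stack = stack, truth = truth, tours = tours, density = dens,
       presences = presences, absences = absences, effort = tours$effort)
}

study_year <- function(month_id) as.integer(substr(month_id, 1, 4))
study_mon <- function(month_id) as.integer(substr(month_id, 6, 7))

#' Run the full synthetic comparison study
#'
#' For every training month: generate the world, build the effort-based
#' pseudo-absences, fit a fresh maximum-entropy model (its weights restart
#' at zero each month) and warm-start-update the network lineage, and
#' cross-validate both. Then run both projection protocols for each
#' projection month. Writes CSV reports and a manifest when
#' `config$out_dir` is set. Months whose inputs fail to generate are
#' skipped with a logged reason.
#'
#' @param config a `study_config`.
#' @return list with `months` (per-month data and reports), `grid`
#'   (`results_grid`), `summary`, `importance`, `projections`, `dl_model`
#'   (the final lineage model), `skipped`.
#' @export
run_study <- function(config) {
  static <- gen_static_layers(config$shape, config$cell_size, config$seed)
  months <- list()
  cells <- data.frame()
  imp_rows <- data.frame()
  dl_model <- NULL
  skipped <- character(0)
  dl_cfg <- config$mlp

  for (i in seq_along(config$train_months)) {
    mid <- config$train_months[i]
    world <- tryCatch(simulate_month(static, mid, config, i),
                      error = function(e) e)
    if (inherits(world, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", mid, conditionMessage(world)))
      next
    }
    tt <- make_training_table(world$stack, world$presences, world$absences)

    fit_fun_me <- function(train) {
      mdl <- fit_maxent(train, beta = config$beta,
                        basis = build_hinge_basis(
                          train, config$knots_per_covariate))
      function(newdata) predict_maxent_points(mdl, newdata)
    }
    me_seed <- derive_seed(config$seed, "cv-me", mid)
    ev_me <- crossval_auc(fit_fun_me, tt, k = config$k, seed = me_seed,
                          model_kind = "maxent")
    me_model <- fit_maxent(tt, beta = config$beta,
                           basis = build_hinge_basis(
                             tt, config$knots_per_covariate))

    prev <- dl_model
    fit_fun_dl <- function(train)
      local({
        mdl <- train_mlp(train, dl_cfg, warm_start = prev)
        function(newdata) predict_mlp_points(mdl, newdata)
      })
    dl_seed <- derive_seed(config$seed, "cv-dl", mid)
    ev_dl <- crossval_auc(fit_fun_dl, tt, k = config$k, seed = dl_seed,
                          model_kind = "dl")
    dl_model <- update_monthly(prev, tt, dl_cfg)

    imp_seed <- derive_seed(config$seed, "imp", mid)
    imp_me <- permutation_importance(
      function(nd) predict_maxent_points(me_model, nd), tt, seed = imp_seed)
    imp_dl <- permutation_importance(
      function(nd) predict_mlp_points(dl_model, nd), tt, seed = imp_seed)

    yr <- study_year(mid); mo <- study_mon(mid)
    cells <- rbind(cells,
                   data.frame(year = yr, model_kind = "maxent", month = mo,
                              auc = ev_me$mean_auc),
                   data.frame(year = yr, model_kind = "dl", month = mo,
                              auc = ev_dl$mean_auc))
    imp_rows <- rbind(imp_rows,
                      cbind(data.frame(month_id = mid, model_kind = "maxent"),
                            as.data.frame(t(imp_me))),
                      cbind(data.frame(month_id = mid, model_kind = "dl"),
                            as.data.frame(t(imp_dl))))
    months[[mid]] <- list(world = world, table = tt, maxent = me_model,
                          eval_maxent = ev_me, eval_dl = ev_dl,
                          importance = list(maxent = imp_me, dl = imp_dl),
                          seed = config$seed)
  }

  mons <- sort(unique(vapply(names(months), study_mon, integer(1))))
  grid <- if (nrow(cells)) results_grid(cells, months = mons) else NULL
  summary <- if (!is.null(grid)) summarize_grid(grid) else NULL

  projections <- list()
  for (pid in config$projection_months) {
    world <- tryCatch(simulate_month(static, pid, config,
                                     length(config$train_months) + 1),
                      error = function(e) e)
    if (inherits(world, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", pid, conditionMessage(world)))
      next
    }
    cal <- study_mon(pid)
    hist_ids <- names(months)[vapply(names(months), study_mon,
                                     integer(1)) == cal]
    if (length(hist_ids)) {
      history <- list(
        presences = lapply(hist_ids, function(h)
          months[[h]]$world$presences),
        absences = lapply(hist_ids, function(h) months[[h]]$world$absences),
        stacks = lapply(hist_ids, function(h) months[[h]]$world$stack))
      projections[[paste0(pid, "/maxent")]] <- project_maxent(
        history, world$stack, world$presences, world$absences,
        beta = config$beta,
        knots_per_covariate = config$knots_per_covariate)
    } else {
      skipped <- c(skipped,
                   sprintf("%s: no historical years for calendar month %02d",
                           pid, cal))
    }
    if (!is.null(dl_model))
      projections[[paste0(pid, "/dl")]] <- project_dl(
        dl_model, world$stack, world$presences, world$absences)
  }

  out <- list(months = months, grid = grid, summary = summary,
              importance = imp_rows, projections = projections,
              dl_model = dl_model, skipped = skipped, config = config)
  if (!is.null(config$out_dir)) write_study_reports(out, config$out_dir)
  out
}

# CSV reports mirroring the monthly-AUC and projection tables, plus a
# manifest; written deterministically so identical configs give identical
# bytes.
write_study_reports <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  grid_path <- file.path(out_dir, "results_grid.csv")
  g <- as.data.frame(unclass(study$grid))
  g <- cbind(row = rownames(study$grid), g,
             average = round(apply(study$grid, 1, mean, na.rm = TRUE), 3))
  utils::write.csv(g, grid_path, row.names = FALSE)
  files <- c(files, grid_path)

  sum_path <- file.path(out_dir, "summary.csv")
  s <- study$summary
  utils::write.csv(data.frame(
    model_kind = names(s$counts_above),
    count_above = as.integer(s$counts_above),
    percent_above = as.integer(s$percent_above),
    average_auc = as.numeric(s$model_averages),
    threshold = s$threshold), sum_path, row.names = FALSE)
  files <- c(files, sum_path)

  imp_path <- file.path(out_dir, "importance.csv")
  utils::write.csv(study$importance, imp_path, row.names = FALSE)
  files <- c(files, imp_path)

  if (length(study$projections)) {
    proj_path <- file.path(out_dir, "projections.csv")
    pr <- do.call(rbind, lapply(study$projections, function(p)
      data.frame(month_id = p$month_id, model_kind = p$model_kind,
                 auc = round(p$auc_vs_actual, 3),
                 n_test_sightings = p$n_test_sightings,
                 low_support = p$low_support_flag)))
    utils::write.csv(pr, proj_path, row.names = FALSE)
    files <- c(files, proj_path)
  }

  eff_path <- file.path(out_dir, "effort.csv")
  write_effort(lapply(study$months, function(m) m$world$effort), eff_path)
  files <- c(files, eff_path)

  cfg <- study$config
  write_manifest(
    file.path(out_dir, "manifest.txt"),
    config = list(train_months = cfg$train_months,
                  projection_months = cfg$projection_months,
                  shape = cfg$shape, cell_size = cfg$cell_size,
                  beta = cfg$beta, knots = cfg$knots_per_covariate,
                  k = cfg$k, bandwidth = cfg$bandwidth),
    seeds = list(master = cfg$seed),
    files = files,
    counts = list(n_months = length(study$months),
                  n_skipped = length(study$skipped),
                  n_projections = length(study$projections)))
  invisible(files)
}
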