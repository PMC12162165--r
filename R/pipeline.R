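#' Leakage-safe per-dog split by video tag
#'
#' Assigns whole videos (never individual chunks) to partitions, per dog:
#' each dog's video tags are shuffled with the seed and allocated to the
#' partitions by cumulative fraction with largest-remainder rounding, so
#' with 10 videos and fractions 80/20 every dog contributes exactly 8
#' train and 2 validation videos. Chunks always inherit their video's
#' partition, which prevents chunk-level information leakage.
#'
#' @param table Feature table from [build_feature_table()] (or any data
#'   frame with `dog_id` and `video_tag` columns).
#' @param fractions Named fractions summing to 1, e.g.
#'   `c(train = 0.8, validation = 0.2)` or
#'   `c(train = 0.7, validation = 0.15, test = 0.15)`.
#' @param seed Integer seed for the per-dog shuffles.
#' @return Object of class `"dataset_split"`: data frame with columns
#'   `video_tag`, `dog_id`, `partition`; attributes `fractions`, `seed`.
#' @export
split_dataset <- function(table, fractions = c(train = 0.8,
                                               validation = 0.2),
                          seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    stop("fractions must be named", call. = FALSE)
  }
  vids <- unique(table[, c("dog_id", "video_tag")])
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs))
  set.seed(as.integer(seed))
  out <- list()
  for (dog in sort(unique(vids$dog_id))) {
    tags <- sort(vids$video_tag[vids$dog_id == dog])
    n <- length(tags)
    if (n < length(fractions)) {
      warning("dog ", dog, " has fewer videos (", n, ") than partitions (",
              length(fractions), "); best-effort assignment", call. = FALSE)
    }
    tags <- sample(tags)
    q <- n * fractions
    base <- floor(q)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    part <- rep(names(fractions), base)
    out[[dog]] <- data.frame(video_tag = tags, dog_id = dog,
                             partition = part, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  structure(res, class = c("dataset_split", "data.frame"),
            fractions = fractions, seed = seed)
}

#' Subset a feature table to one partition of a split
#'
#' @param table Feature table.
#' @param split A [split_dataset()] result.
#' @param partition Partition name (e.g. `"train"`).
#' @return The rows of `table` whose video belongs to `partition`.
#' @export
split_partition <- function(table, split, partition) {
  tags <- split$video_tag[split$partition == partition]
  table[table$video_tag %in% tags, , drop = FALSE]
}

.feature_xy <- function(table, classes = NULL) {
  X <- as.matrix(table[, feature_schema(), drop = FALSE])
  y <- if (is.null(classes)) factor(table$smell)
       else factor(table$smell, levels = classes)
  list(X = X, y = y)
}

.evaluate_cell <- function(model, heldout) {
  # held-out data may contain classes never seen in training (they can
  # never be predicted, so their rows are all off-diagonal)
  classes <- sort(unique(c(model$classes, as.character(heldout$smell))))
  pred <- predict(model, heldout, type = "class")
  cm <- confusion_matrix(as.character(heldout$smell), as.character(pred),
                         classes = classes)
  list(confusion = cm,
       normalized = normalize_rows(cm),
       macro = suppressWarnings(macro_metrics(cm)),
       overall_accuracy = sum(diag(cm)) / sum(cm),
       n = nrow(heldout))
}

#' Experiment configuration
#'
#' @param design A [speckle_design()].
#' @param params A [gbt_params()].
#' @param fractions Split fractions; by default 80/20 train/validation
#'   (pass a three-way split such as
#'   `c(train = .7, validation = .15, test = .15)` to hold out a separate
#'   test partition, which is then used for evaluation).
#' @param seed Master seed for the whole experiment.
#' @param include_control Keep the control class (default `TRUE`).
#' @param chunk_len,stride Chunking, see [chunk_trace()].
#' @param tune_space Optional [param_num()]/[param_int()] space; when
#'   given, `tune_trials` TPE trials maximizing validation macro-F1 pick
#'   the hyperparameters before the final fit.
#' @param tune_trials Number of tuning trials.
#' @return Object of class `"experiment_config"`.
#' @export
experiment_config <- function(design, params = gbt_params(),
                              fractions = c(train = 0.8, validation = 0.2),
                              seed = 1, include_control = TRUE,
                              chunk_len = 40, stride = chunk_len,
                              tune_space = NULL, tune_trials = 20) {
  structure(list(design = design, params = params, fractions = fractions,
                 seed = seed, include_control = include_control,
                 chunk_len = chunk_len, stride = stride,
                 tune_space = tune_space, tune_trials = tune_trials),
            class = "experiment_config")
}

#' Run the full synthetic-experiment pipeline
#'
#' Simulate -> track -> featurize -> split -> (optionally tune) -> train
#' one model per (region, distance) cell -> evaluate on the held-out
#' partition. Evaluation uses the `test` partition when the fractions
#' define one, otherwise `validation`. The whole run is deterministic
#' given the configuration seed.
#'
#' @param config An [experiment_config()].
#' @param feature_table Optionally, a precomputed feature table (the
#'   simulate/track/featurize stages are then skipped).
#' @param out_dir If non-`NULL`, metrics and confusion matrices are
#'   written there as CSV plus a plain-text summary.
#' @return Object of class `"speckle_report"`: list with `cells` (per
#'   region x distance: model, confusion matrices, macro metrics), the
#'   feature `table`, the `split`, `config` and a provenance block.
#' @export
run_experiment <- function(config, feature_table = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(feature_table)) {
    ds <- generate_dataset(config$design, master_seed = config$seed)
    traces <- lapply(ds$videos, track)
    names(traces) <- vapply(ds$videos, `[[`, "", "video_tag")
    feature_table <- build_feature_table(ds$manifest, traces,
                                         config$chunk_len, config$stride)
  }
  tab <- feature_table
  if (!config$include_control) tab <- tab[tab$smell != "control", ,
                                          drop = FALSE]
  split <- split_dataset(tab, config$fractions, seed = config$seed + 1)
  heldout_part <- if ("test" %in% names(config$fractions)) "test"
                  else "validation"

  cells <- list()
  for (region in sort(unique(tab$region))) {
    for (dist in sort(unique(tab$distance_m))) {
      sub <- tab[tab$region == region & tab$distance_m == dist, ,
                 drop = FALSE]
      if (!nrow(sub)) next
      train <- split_partition(sub, split, "train")
      heldout <- split_partition(sub, split, heldout_part)
      if (!nrow(train) || !nrow(heldout)) next
      params <- config$params
      if (!is.null(config$tune_space)) {
        val <- split_partition(sub, split, "validation")
        params <- .tune_cell(train, val, config)
      }
      xy <- .feature_xy(train)
      model <- gbt_fit(xy$X, xy$y, params)
      ev <- .evaluate_cell(model, heldout)
      cells[[sprintf("%s_%gm", region, dist)]] <-
        c(list(region = region, distance_m = dist, model = model,
               n_train = nrow(train), heldout_partition = heldout_part),
          ev)
    }
  }
  report <- structure(list(cells = cells, table = tab, split = split,
                           config = config,
                           provenance = list(
                             seed = config$seed,
                             schema_hash = attr(feature_table,
                                                "schema_hash"),
                             n_rows = nrow(tab),
                             timestamp = NA)),
                      class = "speckle_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

.tune_cell <- function(train, val, config) {
  xy_tr <- .feature_xy(train)
  objective <- function(p) {
    params <- gbt_params(
      eta = if (!is.null(p$eta)) p$eta else config$params$eta,
      max_depth = if (!is.null(p$max_depth)) p$max_depth
                  else config$params$max_depth,
      gamma = if (!is.null(p$gamma)) p$gamma else config$params$gamma,
      lambda_reg = if (!is.null(p$lambda_reg)) p$lambda_reg
                   else config$params$lambda_reg,
      n_rounds = if (!is.null(p$n_rounds)) p$n_rounds
                 else config$params$n_rounds,
      min_child_hessian = config$params$min_child_hessian)
    model <- gbt_fit(xy_tr$X, xy_tr$y, params)
    ev <- .evaluate_cell(model, val)
    f1 <- unclass(ev$macro)[["f1"]]
    if (is.na(f1)) NaN else f1
  }
  log <- tune(config$tune_space, objective, n_trials = config$tune_trials,
              sampler = "tpe", direction = "maximize",
              seed = config$seed + 2)
  bp <- attr(log, "best_params")
  gbt_params(
    eta = if (!is.null(bp$eta)) bp$eta else config$params$eta,
    max_depth = if (!is.null(bp$max_depth)) bp$max_depth
                else config$params$max_depth,
    gamma = if (!is.null(bp$gamma)) bp$gamma else config$params$gamma,
    lambda_reg = if (!is.null(bp$lambda_reg)) bp$lambda_reg
                 else config$params$lambda_reg,
    n_rounds = if (!is.null(bp$n_rounds)) bp$n_rounds
               else config$params$n_rounds,
    min_child_hessian = config$params$min_child_hessian)
}

#' Dog-aggregated analysis for one brain region
#'
#' Pools chunks across all dogs within a region (both distances) before
#' splitting, trains one model on the pooled training videos and
#' evaluates on the pooled held-out videos -- the dog-agnostic confusion
#' matrix and metrics.
#'
#' @param table Feature table containing >= 2 dogs.
#' @param region The brain region to pool.
#' @param params A [gbt_params()].
#' @param fractions,seed Split settings, see [split_dataset()].
#' @return List with `region`, `model`, `confusion`, `normalized`,
#'   `macro`, `n`.
#' @export
aggregate_by_region <- function(table, region, params = gbt_params(),
                                fractions = c(train = 0.8,
                                              validation = 0.2),
                                seed = 1) {
  sub <- table[table$region == region, , drop = FALSE]
  if (!nrow(sub)) stop("region not present: ", region, call. = FALSE)
  if (length(unique(sub$dog_id)) < 2) {
    stop("dog-aggregated analysis requires >= 2 dogs", call. = FALSE)
  }
  split <- split_dataset(sub, fractions, seed)
  heldout_part <- if ("test" %in% names(fractions)) "test"
                  else "validation"
  train <- split_partition(sub, split, "train")
  heldout <- split_partition(sub, split, heldout_part)
  xy <- .feature_xy(train)
  model <- gbt_fit(xy$X, xy$y, params)
  c(list(region = region, model = model), .evaluate_cell(model, heldout))
}

#' Write a report's tables to disk
#'
#' @param report A [run_experiment()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  metric_rows <- list()
  for (nm in names(report$cells)) {
    cell <- report$cells[[nm]]
    utils::write.csv(as.data.frame(unclass(cell$confusion)),
                     file.path(out_dir, paste0("confusion_", nm, ".csv")))
    utils::write.csv(as.data.frame(cell$normalized),
                     file.path(out_dir,
                               paste0("confusion_norm_", nm, ".csv")))
    per <- attr(cell$macro, "per_class")
    for (metric in rownames(per)) {
      for (cl in colnames(per)) {
        metric_rows[[length(metric_rows) + 1]] <- data.frame(
          region = cell$region, distance_m = cell$distance_m, class = cl,
          metric = metric, value = per[metric, cl])
      }
      metric_rows[[length(metric_rows) + 1]] <- data.frame(
        region = cell$region, distance_m = cell$distance_m,
        class = "macro", metric = metric,
        value = unclass(cell$macro)[[metric]])
    }
  }
  if (length(metric_rows)) {
    utils::write.csv(do.call(rbind, metric_rows),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  summ <- utils::capture.output(print(report))
  writeLines(summ, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.speckle_report <- function(x, ...) {
  cat("Speckle classification experiment report\n")
  cat(sprintf("  seed %d | %d feature rows | schema %s\n",
              x$provenance$seed, x$provenance$n_rows,
              substr(x$provenance$schema_hash, 1, 8)))
  for (nm in names(x$cells)) {
    cell <- x$cells[[nm]]
    mm <- unclass(cell$macro)
    cat(sprintf(
      "  %-28s heldout n=%3d  acc %.2f  macro: prec %.2f  sens %.2f  spec %.2f  F1 %.2f\n",
      nm, cell$n, cell$overall_accuracy, mm["precision"],
      mm["sensitivity"], mm["specificity"], mm["f1"]))
  }
  invisible(x)
}
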