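# Fitness evaluation: data splits, the per-class screening subsample, the
# genome -> trained-accuracy fitness function, and the two-stage search
# protocol (cheap screening during the swarm search, then full training of
# the winner).

#' Data split specification
#'
#' The protocol splits 80/20 into a training pool and a test set, then sets
#' aside 10% of the pool for validation.
#'
#' @param test_fraction Fraction of the data held out for testing.
#' @param validation_fraction Fraction of the training pool set aside for
#'   validation.
#' @param stratified Preserve class proportions within each split (within
#'   one sample per class).
#' @param seed Split seed.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, validation_fraction = 0.1,
                       stratified = TRUE, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

# Allocate round(frac * n) indices out of `idx`, stratified by label:
# per-class quotas are the largest-remainder apportionment of the total,
# which keeps proportions within one sample per class.
.strat_take <- function(idx, labels, frac) {
  total <- round(frac * length(idx))
  cls <- split(idx, labels[idx])
  quota_real <- vapply(cls, length, numeric(1)) * total / length(idx)
  quota <- floor(quota_real)
  rem <- total - sum(quota)
  if (rem > 0) {
    extra <- order(quota_real - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1
  }
  take <- unlist(mapply(function(members, q) {
    if (q > length(members)) q <- length(members)
    sample(members, q)
  }, cls, quota, SIMPLIFY = FALSE), use.names = FALSE)
  take
}

#' Split a dataset into train / validation / test
#'
#' `round(test_fraction * N)` samples form the test set;
#' `round(validation_fraction * |pool|)` of the remaining pool form the
#' validation set; the rest train. Stratification keeps per-class
#' proportions within one sample of the overall rate. Deterministic under
#' the spec seed; the three parts are disjoint and exhaustive.
#'
#' @param ds An `image_dataset` (every class needs >= 2 samples when
#'   stratified).
#' @param spec A [split_spec()].
#' @return List of `image_dataset`s: `train`, `validation`, `test`.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "image_dataset"), inherits(spec, "split_spec"))
  n <- length(ds$labels)
  if (n == 0) stop("dataset is empty", call. = FALSE)
  if (spec$stratified) {
    counts <- class_counts(ds)
    ones <- names(counts)[counts == 1]
    if (length(ones))
      stop("stratified split impossible: class(es) with a single sample: ",
           paste(ones, collapse = ", "), call. = FALSE)
  }
  local_seed(spec$seed, {
    all_idx <- seq_len(n)
    test <- if (spec$stratified)
      .strat_take(all_idx, ds$labels, spec$test_fraction)
    else sample(all_idx, round(spec$test_fraction * n))
    pool <- setdiff(all_idx, test)
    val <- if (spec$stratified)
      .strat_take(pool, ds$labels, spec$validation_fraction)
    else sample(pool, round(spec$validation_fraction * length(pool)))
    train <- setdiff(pool, val)
    list(train = dataset_subset(ds, sort(train)),
         validation = dataset_subset(ds, sort(val)),
         test = dataset_subset(ds, sort(test)))
  })
}

#' Screening subsample with a fixed count per class
#'
#' Takes `min(n_per_class, class size)` images from every class (with a
#' warning for short classes); deterministic under the seed.
#'
#' @param ds An `image_dataset`.
#' @param n_per_class Target per-class count (the screening stage uses 200).
#' @param seed Subsample seed.
#' @return The subsampled `image_dataset`.
#' @export
subsample_per_class <- function(ds, n_per_class = 200, seed = 1) {
  stopifnot(inherits(ds, "image_dataset"))
  local_seed(seed, {
    keep <- unlist(lapply(seq_along(ds$class_names), function(k) {
      members <- which(ds$labels == k)
      if (length(members) < n_per_class) {
        warning("class '", ds$class_names[k], "' has only ",
                length(members), " samples (< ", n_per_class, "); taking all",
                call. = FALSE)
        members
      } else sample(members, n_per_class)
    }), use.names = FALSE)
    dataset_subset(ds, sort(keep))
  })
}

#' Fitness of one genome: classification error of the trained candidate
#'
#' The total pipeline behind each swarm evaluation: decode -> repair ->
#' budget feasibility (fail => worst-case fitness 1) -> train on the train
#' split with validation monitoring -> measure accuracy on the fitness
#' split -> return `L = 1 - accuracy`. Never raises: training failures map
#' to 1 with a warning. The study protocol measures fitness on the test
#' split; `fitness_split = "validation"` keeps the test set untouched
#' during the search and is the recommended mode (see the methods
#' vignette).
#'
#' @param genome Numeric vector in `[0, 1]` of layout length.
#' @param layout A [build_layout()] result.
#' @param splits A [split_dataset()] result.
#' @param train_cfg A [train_config()].
#' @param budget Feasibility budget (see [feasibility_check()]).
#' @param num_classes Number of classes.
#' @param fitness_split `"test"` or `"validation"`.
#' @return Fitness in `[0, 1]`; `attr(, "arch")` carries the repaired
#'   architecture, `attr(, "accuracy")` the measured accuracy.
#' @export
nas_fitness <- function(genome, layout, splits, train_cfg,
                        budget = list(max_parameters = 2e7,
                                      max_activation_cells = 5e7),
                        num_classes = length(splits$train$class_names),
                        fitness_split = c("test", "validation")) {
  fitness_split <- match.arg(fitness_split)
  shape <- dim(splits$train$images)[1:3]
  arch <- tryCatch(
    repair_architecture(decode_architecture(genome, layout, shape,
                                            num_classes)),
    error = function(e) NULL)
  if (is.null(arch)) return(structure(1, accuracy = 0))
  feas <- feasibility_check(arch, budget)
  if (!feas$pass)
    return(structure(1, arch = arch, accuracy = 0,
                     infeasible = feas$violated))
  model <- tryCatch(
    train_model(arch, splits$train, splits$validation, train_cfg),
    error = function(e) NULL)
  if (is.null(model) || !isTRUE(model$ok))
    return(structure(1, arch = arch, accuracy = 0))
  eval_ds <- if (fitness_split == "test") splits$test else splits$validation
  probs <- predict(model, eval_ds)
  acc <- mean(max.col(probs, ties.method = "first") == eval_ds$labels)
  structure(1 - acc, arch = arch, accuracy = acc)
}

#' Two-stage architecture search
#'
#' Stage 1 screens candidates cheaply: the swarm's fitness trains each
#' decoded architecture for a few epochs (`screen_cfg`) on a per-class
#' subsample (200 per class at full scale). Stage 2 retrains the best
#' architecture with the full protocol (`final_cfg`) on the complete
#' dataset and produces the final evaluation report.
#'
#' @param ds The (balanced) `image_dataset`.
#' @param config A [swarm_config()].
#' @param layout A [build_layout()] result.
#' @param screen_cfg,final_cfg [train_config()]s for the two stages.
#' @param budget Feasibility budget.
#' @param split A [split_spec()].
#' @param n_screen_per_class Screening subsample size per class.
#' @param fitness_split Split on which stage-1 fitness is measured.
#' @return List: `best_arch` (repaired), `best_genome`, `report` (stage-2
#'   [evaluate_model()] result), `history` (stage-1 convergence),
#'   `model` (the stage-2 `nas_model`), `evaluations`.
#' @export
two_stage_search <- function(ds, config, layout,
                             screen_cfg = train_config(epochs = 5),
                             final_cfg = train_config(epochs = 50),
                             budget = list(max_parameters = 2e7,
                                           max_activation_cells = 5e7),
                             split = split_spec(),
                             n_screen_per_class = 200,
                             fitness_split = "test") {
  sub <- subsample_per_class(ds, n_screen_per_class,
                             seed = derive_seed(config$seed, 11))
  sub_split <- split_dataset(sub, split)
  fitness_fn <- function(genome)
    as.numeric(nas_fitness(genome, layout, sub_split, screen_cfg, budget,
                           fitness_split = fitness_split))
  res <- pso_run(config, layout, fitness_fn)
  shape <- dim(ds$images)[1:3]
  best_arch <- repair_architecture(
    decode_architecture(res$best_genome, layout, shape,
                        length(ds$class_names)))
  full_split <- split_dataset(ds, split)
  model <- train_model(best_arch, full_split$train, full_split$validation,
                       final_cfg)
  report <- evaluate_model(model, full_split$test)
  list(best_arch = best_arch, best_genome = res$best_genome,
       best_screen_fitness = res$best_fitness, report = report,
       history = res$history, model = model,
       evaluations = res$evaluations)
}
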