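# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small fixture builders. Everything here is written
# per-sample / per-pair on purpose: slow but transparently correct.

# Per-sample one-vs-rest counting for each class.
brute_metrics <- function(y_true, y_pred, K) {
  n <- length(y_true)
  per <- lapply(seq_len(K), function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    tn <- sum(y_true != k & y_pred != k)
    safe <- function(num, den) if (den > 0) num / den else 0
    c(precision = safe(tp, tp + fp), recall = safe(tp, tp + fn),
      f1 = safe(2 * tp, 2 * tp + fp + fn),
      specificity = safe(tn, tn + fp), accuracy = safe(tp + tn, n))
  })
  list(per_class = do.call(rbind, per),
       overall_accuracy = mean(y_true == y_pred))
}

# Chance-corrected agreement computed from raw label vectors.
brute_kappa <- function(y_true, y_pred, K) {
  n <- length(y_true)
  po <- mean(y_true == y_pred)
  pe <- sum(vapply(seq_len(K), function(k)
    sum(y_true == k) * sum(y_pred == k), numeric(1))) / n^2
  (po - pe) / (1 - pe)
}

# AUC by exhaustive positive/negative pair comparison (ties count 1/2).
brute_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Toy minimization target for the swarm: mean squared distance to 0.5.
sphere_fitness <- function(x) mean((x - 0.5)^2)

# Small balanced synthetic dataset.
tiny_dataset <- function(n_classes = 2, image_size = 8, n_per_class = 30,
                         seed = 1, separability = 1) {
  generate_synthetic(synthetic_spec(
    n_classes = n_classes, image_size = image_size,
    per_class_counts = rep(n_per_class, n_classes),
    separability = separability, seed = seed))
}

# A small fixed architecture matching tiny_dataset's shape.
tiny_arch <- function(image_size = 8, n_classes = 2, filters = 8) {
  architecture_spec(c(image_size, image_size, 3), list(
    list(type = "conv", filter_size = 3, num_filters = filters, stride = 1),
    list(type = "pool", pool_type = "max", filter_size = 2, stride = 2)),
    n_classes)
}
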