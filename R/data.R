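# Datasets: class-conditional synthetic image generator (the desk-scale
# stand-in for dermoscopy photographs), a HAM10000-style folder/CSV reader,
# and the class-balancing planner with pluggable oversampling (the seat a
# trained conditional generator would occupy).

#' Image dataset container
#'
#' @param images Numeric array `(H, W, C, N)` of intensities in 0..255.
#' @param labels Integer labels in `1..K`.
#' @param class_names Character vector of K class names.
#' @param provenance Per-image flag, `"original"` or `"synthetic"`.
#' @return Object of class `image_dataset`.
#' @export
image_dataset <- function(images, labels, class_names,
                          provenance = rep("original", length(labels))) {
  d <- dim(images)
  if (length(d) != 4) stop("images must be a (H, W, C, N) array", call. = FALSE)
  if (d[4] != length(labels))
    stop("|images| != |labels|", call. = FALSE)
  if (length(provenance) != length(labels))
    stop("|provenance| != |labels|", call. = FALSE)
  if (length(class_names) < 2) stop("need K >= 2 classes", call. = FALSE)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > length(class_names)))
    stop("labels out of range 1..K", call. = FALSE)
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 provenance = provenance),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_dataset> %d images %dx%dx%d, %d classes\n",
              d[4], d[1], d[2], d[3], length(x$class_names)))
  print(class_counts(x))
  invisible(x)
}

#' Per-class image counts
#' @param ds An `image_dataset`.
#' @return Named integer vector (one entry per class, zeros included).
#' @export
class_counts <- function(ds) {
  out <- integer(length(ds$class_names))
  names(out) <- ds$class_names
  tab <- table(factor(ds$labels, levels = seq_along(ds$class_names)))
  out[] <- as.integer(tab)
  out
}

#' Subset an image dataset by index
#' @param ds An `image_dataset`.
#' @param idx Integer indices into the images.
#' @return The subsetted `image_dataset`.
#' @export
dataset_subset <- function(ds, idx) {
  image_dataset(ds$images[, , , idx, drop = FALSE], ds$labels[idx],
                ds$class_names, ds$provenance[idx])
}

#' Synthetic dataset specification
#'
#' @param n_classes Number of classes K (>= 2).
#' @param image_size Height = width in pixels.
#' @param channels Image channels (3 for RGB).
#' @param per_class_counts Integer vector of K per-class counts.
#' @param noise_sigma Gaussian pixel-noise standard deviation (intensity
#'   units, 0..255 scale).
#' @param separability Real in (0, 1] scaling the class-specific pattern
#'   amplitude: 1 is the calibrated easy regime, values near 0 approach
#'   unlearnable (accuracy ~ 1/K).
#' @param seed Generator seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 7, image_size = 32, channels = 3,
                           per_class_counts = rep(100, n_classes),
                           noise_sigma = 8, separability = 1, seed = 1) {
  if (n_classes < 2 || image_size < 1)
    stop("need n_classes >= 2 and image_size >= 1", call. = FALSE)
  if (length(per_class_counts) != n_classes)
    stop("per_class_counts must have one entry per class", call. = FALSE)
  stopifnot(all(per_class_counts >= 0), noise_sigma >= 0,
            separability > 0, separability <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 per_class_counts = as.integer(per_class_counts),
                 noise_sigma = noise_sigma, separability = separability,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Deterministic class signature: oriented stripes whose angle and spatial
# frequency are keyed to the class, a Gaussian blob at a class-specific
# position, and a class-specific channel mix. Values roughly in [-1, 1].
.class_pattern <- function(k, K, H, W, C) {
  theta <- pi * (k - 1) / K
  freq <- 2 + (k - 1) %% 3
  xs <- matrix(rep(seq_len(W), each = H), H, W) / W
  ys <- matrix(rep(seq_len(H), times = W), H, W) / H
  stripes <- sin(2 * pi * freq * (xs * cos(theta) + ys * sin(theta)))
  cx <- 0.5 + 0.3 * cos(2 * pi * (k - 1) / K)
  cy <- 0.5 + 0.3 * sin(2 * pi * (k - 1) / K)
  blob <- exp(-(((xs - cx)^2 + (ys - cy)^2) / (2 * 0.15^2)))
  base <- 0.6 * stripes + 0.8 * blob
  pat <- array(0, c(H, W, C))
  for (ch in seq_len(C)) {
    wch <- 0.5 + 0.5 * cos(theta + 2 * pi * (ch - 1) / max(C, 1))
    pat[, , ch] <- wch * base
  }
  pat
}

#' Generate a class-conditional synthetic image dataset
#'
#' Class k's images share a deterministic parametric pattern (oriented
#' stripes with class-keyed angle and frequency, a class-positioned blob,
#' and a class-specific channel mix), scaled by `separability`, plus
#' i.i.d. Gaussian pixel noise of sd `noise_sigma`; intensities are clipped
#' to 0..255 and quantized. Bit-reproducible under the spec seed. At
#' `separability = 1` a small CNN separates the classes almost perfectly;
#' as `separability -> 0` accuracy approaches `1/K`.
#'
#' @param spec A [synthetic_spec()].
#' @return An `image_dataset` with class names `class01`, `class02`, ...
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_size; W <- spec$image_size; C <- spec$channels
  K <- spec$n_classes
  n <- sum(spec$per_class_counts)
  if (n == 0) stop("no images requested", call. = FALSE)
  local_seed(spec$seed, {
    images <- array(0, c(H, W, C, n))
    labels <- integer(n)
    amplitude <- 100 * spec$separability
    i <- 1
    for (k in seq_len(K)) {
      pat <- .class_pattern(k, K, H, W, C)
      for (j in seq_len(spec$per_class_counts[k])) {
        img <- 127.5 + amplitude * pat +
          array(rnorm(H * W * C, sd = spec$noise_sigma), c(H, W, C))
        images[, , , i] <- round(pmin(pmax(img, 0), 255))
        labels[i] <- k
        i <- i + 1
      }
    }
    image_dataset(images, labels, sprintf("class%02d", seq_len(K)))
  })
}

#' Read a HAM10000-style image folder
#'
#' Expects a metadata CSV with columns `image_id` and `dx` (the lesion
#' class, e.g. akiec/bcc/bkl/df/nv/vasc/mel) and one raster file
#' (`<image_id>.png`/`.jpg`/`.jpeg`/`.tif`) per row in `image_dir`. Images
#' are resized to `input_size` with bilinear (antialiased) interpolation;
#' labels are mapped by sorted class-name order. Unknown labels and missing
#' files fail hard: silently dropped rows would corrupt stratification.
#'
#' @param image_dir Directory of raster images.
#' @param labels_csv Path to the metadata CSV.
#' @param input_size Target height = width (e.g. 32, 128, 224).
#' @param classes Optional fixed class-name set; rows with a `dx` outside
#'   it are an error.
#' @return An `image_dataset`.
#' @export
load_image_folder <- function(image_dir, labels_csv, input_size = 32,
                              classes = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("load_image_folder requires the EBImage package", call. = FALSE)
  meta <- read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("image_id", "dx") %in% names(meta)))
    stop("labels CSV must have columns 'image_id' and 'dx'", call. = FALSE)
  class_names <- if (is.null(classes)) sort(unique(meta$dx)) else sort(classes)
  unknown <- setdiff(unique(meta$dx), class_names)
  if (length(unknown))
    stop("unknown label(s) in CSV: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  paths <- vapply(meta$image_id, function(id) {
    for (ext in c(".png", ".jpg", ".jpeg", ".tif", ".tiff")) {
      p <- file.path(image_dir, paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  if (anyNA(paths))
    stop("missing image file(s) for id(s): ",
         paste(meta$image_id[is.na(paths)], collapse = ", "), call. = FALSE)
  n <- nrow(meta)
  images <- array(0, c(input_size, input_size, 3, n))
  for (i in seq_len(n)) {
    img <- EBImage::readImage(paths[i])
    img <- EBImage::resize(img, w = input_size, h = input_size,
                           antialias = TRUE)
    a <- as.array(img)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    # EBImage stores (x, y, c) in 0..1; our arrays are (row, col, c) 0..255
    images[, , , i] <- aperm(a, c(2, 1, 3)) * 255
  }
  labels <- match(meta$dx, class_names)
  image_dataset(images, labels, class_names)
}

#' Plan class balancing to the majority class
#'
#' Sets the target to the majority class count and the per-class additions
#' to `target - count`, so every class ends at the majority size (the
#' majority class itself receives zero additions).
#'
#' @param class_counts Named or unnamed nonnegative integer vector.
#' @return Object of class `balance_plan`: `target_per_class`, `additions`.
#' @export
balance_plan <- function(class_counts) {
  if (!length(class_counts) || any(class_counts < 0))
    stop("class counts must be nonnegative and nonempty", call. = FALSE)
  if (max(class_counts) == 0)
    stop("all class counts are zero", call. = FALSE)
  target <- max(class_counts)
  structure(list(target_per_class = as.integer(target),
                 additions = as.integer(target - class_counts),
                 original_counts = as.integer(class_counts),
                 names = names(class_counts)),
            class = "balance_plan")
}

# flips / 90-degree rotations / intensity jitter of one (H, W, C) image.
.augment_image <- function(img) {
  if (runif(1) < 0.5) img <- img[dim(img)[1]:1, , , drop = FALSE]
  if (runif(1) < 0.5) img <- img[, dim(img)[2]:1, , drop = FALSE]
  k <- sample(0:3, 1)
  if (k > 0) for (r in seq_len(k)) img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  gain <- runif(1, 0.85, 1.15)
  shift <- runif(1, -10, 10)
  pmin(pmax(img * gain + shift, 0), 255)
}

#' Oversample minority classes to a balance plan
#'
#' Appends `additions[k]` synthetic images per class. The default
#' `"transform"` strategy oversamples class-k originals with random flips,
#' right-angle rotations and intensity jitter. Alternatively a conditional
#' generator can be plugged in: any `function(class_index, n)` returning an
#' `(H, W, C, n)` intensity array (the interface a trained conditional GAN
#' would honor). All appended images are flagged `"synthetic"`.
#'
#' @param ds An `image_dataset`.
#' @param plan A [balance_plan()] consistent with `ds`'s counts.
#' @param strategy `"transform"` or `"generator"`.
#' @param seed RNG seed for the oversampling draws.
#' @param generator The conditional generator function (required when
#'   `strategy = "generator"`).
#' @return The balanced `image_dataset` (all class counts equal the
#'   plan's target).
#' @export
balance_dataset <- function(ds, plan, strategy = c("transform", "generator"),
                            seed = 1, generator = NULL) {
  stopifnot(inherits(ds, "image_dataset"), inherits(plan, "balance_plan"))
  strategy <- match.arg(strategy)
  counts <- class_counts(ds)
  if (length(counts) != length(plan$additions) ||
      any(counts != plan$original_counts))
    stop("balance plan does not match the dataset's class counts",
         call. = FALSE)
  if (strategy == "generator" && !is.function(generator))
    stop("strategy 'generator' requires a generator function", call. = FALSE)
  if (all(plan$additions == 0)) return(ds)
  d <- dim(ds$images)
  local_seed(seed, {
    new_imgs <- list()
    new_labels <- integer(0)
    for (k in seq_along(plan$additions)) {
      nadd <- plan$additions[k]
      if (nadd == 0) next
      if (strategy == "transform") {
        pool <- which(ds$labels == k)
        if (!length(pool))
          stop("class '", ds$class_names[k],
               "' has no originals to oversample from", call. = FALSE)
        src <- sample(pool, nadd, replace = TRUE)
        gen <- array(0, c(d[1], d[2], d[3], nadd))
        for (j in seq_len(nadd))
          gen[, , , j] <- .augment_image(
            ds$images[, , , src[j], drop = FALSE][, , , 1])
      } else {
        gen <- generator(k, nadd)
        if (!all(dim(gen) == c(d[1], d[2], d[3], nadd)))
          stop("generator returned wrong shape for class ", k, call. = FALSE)
      }
      new_imgs[[length(new_imgs) + 1]] <- gen
      new_labels <- c(new_labels, rep(k, nadd))
    }
    total_new <- length(new_labels)
    images <- array(0, c(d[1], d[2], d[3], d[4] + total_new))
    images[, , , seq_len(d[4])] <- ds$images
    off <- d[4]
    for (g in new_imgs) {
      nn <- dim(g)[4]
      images[, , , off + seq_len(nn)] <- g
      off <- off + nn
    }
    image_dataset(images, c(ds$labels, new_labels), ds$class_names,
                  c(ds$provenance, rep("synthetic", total_new)))
  })
}

#' Write a dataset manifest CSV
#'
#' @param ds An `image_dataset`.
#' @param path Output CSV path (columns: index, label, class, provenance).
#' @export
write_manifest <- function(ds, path) {
  write.csv(data.frame(index = seq_along(ds$labels), label = ds$labels,
                       class = ds$class_names[ds$labels],
                       provenance = ds$provenance),
            path, row.names = FALSE)
}
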