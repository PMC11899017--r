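test_that("the synthetic generator honors counts, shapes and determinism", {
  ds <- generate_synthetic(synthetic_spec(n_classes = 4, image_size = 16,
                                          per_class_counts = rep(50, 4),
                                          seed = 1))
  expect_equal(length(ds$labels), 200)
  expect_equal(dim(ds$images), c(16, 16, 3, 200))
  expect_equal(unname(class_counts(ds)), rep(50, 4))
  expect_true(all(ds$images >= 0 & ds$images <= 255))
  ds2 <- generate_synthetic(synthetic_spec(n_classes = 4, image_size = 16,
                                           per_class_counts = rep(50, 4),
                                           seed = 1))
  expect_identical(ds$images, ds2$images)  # bit-reproducible
  expect_error(generate_synthetic(synthetic_spec(per_class_counts =
                                                   rep(0, 7))),
               "no images")
})

test_that("noise-free fully-separable classes are pixel-identical within class", {
  ds <- generate_synthetic(synthetic_spec(n_classes = 3, image_size = 8,
                                          per_class_counts = rep(4, 3),
                                          noise_sigma = 0, separability = 1,
                                          seed = 2))
  for (k in 1:3) {
    idx <- which(ds$labels == k)
    first <- ds$images[, , , idx[1]]
    for (j in idx[-1]) expect_identical(ds$images[, , , j], first)
  }
  # different classes differ
  expect_false(identical(ds$images[, , , 1],
                         ds$images[, , , which(ds$labels == 2)[1]]))
})

test_that("balance planning raises every class to the majority count", {
  ham <- c(nv = 6705, mel = 1113, bkl = 1099, bcc = 514, akiec = 327,
           vasc = 142, df = 115)
  plan <- balance_plan(ham)
  expect_equal(plan$target_per_class, 6705)
  expect_equal(plan$additions,
               c(0, 5592, 5606, 6191, 6378, 6563, 6590))
  expect_equal(plan$original_counts + plan$additions,
               rep(6705L, 7))
  expect_equal(balance_plan(c(5, 5, 5))$additions, rep(0L, 3))
  expect_equal(balance_plan(c(3, 10))$additions, c(7L, 0L))
  expect_error(balance_plan(c(0, 0)), "zero")
  expect_error(balance_plan(integer(0)), "nonempty")
})

test_that("transform oversampling reaches the target with provenance flags", {
  ds <- generate_synthetic(synthetic_spec(n_classes = 2, image_size = 8,
                                          per_class_counts = c(3, 10),
                                          seed = 3))
  plan <- balance_plan(class_counts(ds))
  bal <- balance_dataset(ds, plan, seed = 4)
  expect_equal(unname(class_counts(bal)), c(10, 10))
  expect_equal(sum(bal$provenance == "synthetic"), 7)
  # originals conserved
  expect_equal(sum(bal$provenance == "original"), 13)
  expect_identical(bal$images[, , , 1:13], ds$images)
  # zero-addition plan returns the dataset unchanged
  even <- generate_synthetic(synthetic_spec(n_classes = 2, image_size = 8,
                                            per_class_counts = c(5, 5),
                                            seed = 5))
  expect_identical(balance_dataset(even, balance_plan(class_counts(even))),
                   even)
})

test_that("balancing a skewed 7-class dataset equalizes at the scaled majority", {
  # the dermoscopy class ratio scaled down ~50x
  counts <- c(134, 22, 22, 10, 7, 3, 2)
  ds <- generate_synthetic(synthetic_spec(n_classes = 7, image_size = 8,
                                          per_class_counts = counts,
                                          seed = 6))
  bal <- balance_dataset(ds, balance_plan(class_counts(ds)), seed = 7)
  expect_equal(unname(class_counts(bal)), rep(134, 7))
})

test_that("the conditional-generator seat accepts a plug-in generator", {
  ds <- generate_synthetic(synthetic_spec(n_classes = 2, image_size = 8,
                                          per_class_counts = c(4, 9),
                                          seed = 8))
  gen <- function(class_index, n) array(class_index * 10, c(8, 8, 3, n))
  bal <- balance_dataset(ds, balance_plan(class_counts(ds)),
                         strategy = "generator", generator = gen)
  expect_equal(unname(class_counts(bal)), c(9, 9))
  made <- bal$images[, , , bal$provenance == "synthetic", drop = FALSE]
  expect_true(all(made == 10))
  expect_error(balance_dataset(ds, balance_plan(class_counts(ds)),
                               strategy = "generator"),
               "generator function")
})

test_that("a class without originals cannot be transform-oversampled", {
  imgs <- array(runif(8 * 8 * 3 * 5, 0, 255), c(8, 8, 3, 5))
  ds <- image_dataset(imgs, rep(2, 5), c("empty", "full"))
  plan <- balance_plan(class_counts(ds))
  expect_error(balance_dataset(ds, plan), "empty")
})

test_that("the folder/CSV reader loads, resizes and maps labels", {
  skip_if_not_installed("png")
  skip_if_not_installed("EBImage")
  dir <- withr::local_tempdir()
  classes <- c("akiec", "bcc", "bkl", "df", "mel", "nv", "vasc")
  set.seed(9)
  ids <- character(0)
  dx <- character(0)
  for (k in seq_along(classes)) for (j in 1:2) {
    id <- sprintf("img_%s_%d", classes[k], j)
    # 10 x 8 source images to exercise the resize path
    png::writePNG(array(runif(10 * 8 * 3), c(10, 8, 3)),
                  file.path(dir, paste0(id, ".png")))
    ids <- c(ids, id); dx <- c(dx, classes[k])
  }
  csv <- file.path(dir, "labels.csv")
  write.csv(data.frame(image_id = ids, dx = dx), csv, row.names = FALSE)
  ds <- load_image_folder(dir, csv, input_size = 8)
  expect_equal(length(ds$labels), 14)
  expect_equal(ds$class_names, sort(classes))
  expect_equal(dim(ds$images), c(8, 8, 3, 14))
  expect_equal(unname(class_counts(ds)), rep(2, 7))
  # a CSV row without its image file names the id
  write.csv(data.frame(image_id = c(ids, "ghost_01"), dx = c(dx, "nv")),
            csv, row.names = FALSE)
  expect_error(load_image_folder(dir, csv, input_size = 8), "ghost_01")
  # unknown labels fail hard
  write.csv(data.frame(image_id = ids[1], dx = "mystery"), csv,
            row.names = FALSE)
  expect_error(load_image_folder(dir, csv, input_size = 8,
                                 classes = classes), "mystery")
})

test_that("the dataset manifest records label and provenance per image", {
  ds <- generate_synthetic(synthetic_spec(n_classes = 2, image_size = 4,
                                          per_class_counts = c(2, 3),
                                          seed = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(ds, path)
  m <- read.csv(path)
  expect_equal(nrow(m), 5)
  expect_equal(m$provenance, rep("original", 5))
  expect_equal(m$class, ds$class_names[ds$labels])
})
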