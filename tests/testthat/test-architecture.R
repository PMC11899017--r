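# Builds genomes through the inverse mapping so decode tests do not depend
# on hand-tuned raw coordinates.
genome_for <- function(layout, assignments) {
  g <- numeric(layout$D)
  gm <- layout$gene_map
  for (a in assignments) {
    i <- which(gm$slot_type == a$st & gm$slot == a$slot & gm$gene == a$gene)
    g[i] <- normalize_value(a$value, layout$config$ranges[[a$gene]])
  }
  g
}

test_that("control genes select serial vs multi-branch and pooling on/off", {
  layout <- build_layout(search_space_config(max_macro_layers = 1,
                                             fc_slots = 1))
  g <- genome_for(layout, list(
    list(st = "macro", slot = 1, gene = "conv_control", value = 2),
    list(st = "macro", slot = 1, gene = "mb_nb", value = 3),
    list(st = "macro", slot = 1, gene = "mb_nf", value = 87),
    list(st = "macro", slot = 1, gene = "pool_control", value = 0),
    list(st = "fc", slot = 1, gene = "fc_control", value = 0)))
  arch <- decode_architecture(g, layout, c(32, 32, 3), 7)
  expect_length(arch$layers, 1)
  ly <- arch$layers[[1]]
  expect_equal(ly$type, "multibranch")
  expect_equal(ly$num_branches, 3L)
  expect_equal(ly$filters_per_branch, 87L)
  expect_identical(ly$branch_kernels, c(1L, 3L, 5L))

  g2 <- genome_for(layout, list(
    list(st = "macro", slot = 1, gene = "conv_control", value = 1),
    list(st = "macro", slot = 1, gene = "conv_fs", value = 5),
    list(st = "macro", slot = 1, gene = "conv_nf", value = 64),
    list(st = "macro", slot = 1, gene = "conv_stride", value = 2),
    list(st = "macro", slot = 1, gene = "pool_control", value = 1),
    list(st = "macro", slot = 1, gene = "pool_type", value = 2),
    list(st = "macro", slot = 1, gene = "pool_fs", value = 3),
    list(st = "macro", slot = 1, gene = "pool_stride", value = 2),
    list(st = "fc", slot = 1, gene = "fc_control", value = 1),
    list(st = "fc", slot = 1, gene = "fc_nn", value = 40)))
  arch2 <- decode_architecture(g2, layout, c(32, 32, 3), 7)
  types <- vapply(arch2$layers, `[[`, character(1), "type")
  expect_identical(types, c("conv", "pool", "fc"))
  expect_equal(arch2$layers[[2]]$pool_type, "avg")
  expect_equal(arch2$layers[[3]]$num_neurons, 40L)
})

test_that("decoding is deterministic and validates genome length", {
  layout <- build_layout(search_space_config(max_macro_layers = 2))
  g <- random_genome(layout, seed = 3)
  a1 <- decode_architecture(g, layout, c(16, 16, 3), 4)
  a2 <- decode_architecture(g, layout, c(16, 16, 3), 4)
  expect_identical(a1, a2)
  expect_error(decode_architecture(g[-1], layout, c(16, 16, 3), 4),
               "decode error")
})

test_that("shape propagation follows SAME-conv / VALID-pool conventions", {
  a <- architecture_spec(c(110, 110, 3), list(
    list(type = "conv", filter_size = 6, num_filters = 4, stride = 2)), 2)
  tb <- propagate_shapes(a)
  expect_equal(tb$out_h[1], 55)
  a2 <- architecture_spec(c(26, 26, 3), list(
    list(type = "conv", filter_size = 7, num_filters = 4, stride = 1),
    list(type = "pool", pool_type = "max", filter_size = 4, stride = 2)), 2)
  tb2 <- propagate_shapes(a2)
  expect_equal(tb2$out_h[1], 26)  # stride-1 SAME conv preserves extent
  expect_equal(tb2$out_h[2], 12)  # floor((26-4)/2)+1
})

test_that("multibranch concatenation channels equal NB x NF", {
  for (cfg in list(c(3, 87, 261), c(4, 102, 408), c(3, 41, 123),
                   c(3, 28, 84))) {
    a <- architecture_spec(c(8, 8, 3), list(
      list(type = "multibranch", num_branches = cfg[1],
           filters_per_branch = cfg[2],
           branch_kernels = 2L * seq_len(cfg[1]) - 1L)), 2)
    expect_equal(propagate_shapes(a)$out_c[1], cfg[3])
  }
})

test_that("repair removes oversized pooling windows and is idempotent", {
  a <- architecture_spec(c(4, 4, 3), list(
    list(type = "pool", pool_type = "max", filter_size = 7, stride = 3),
    list(type = "conv", filter_size = 3, num_filters = 4, stride = 1)), 2)
  r <- repair_architecture(a)
  expect_length(r$layers, 1)
  expect_equal(r$layers[[1]]$type, "conv")
  expect_match(attr(r, "repair_log"), "removed layer 1")
  ok <- architecture_spec(c(16, 16, 3), list(
    list(type = "pool", pool_type = "avg", filter_size = 2, stride = 2)), 2)
  expect_identical(repair_architecture(ok)$layers, ok$layers)
  expect_identical(repair_architecture(repair_architecture(a))$layers,
                   r$layers)
})

test_that("every repaired random genome passes shape propagation", {
  layout <- build_layout(search_space_config(max_macro_layers = 5))
  for (s in 1:300) {
    g <- random_genome(layout, seed = s)
    arch <- repair_architecture(decode_architecture(g, layout, c(16, 16, 3),
                                                    4))
    tb <- propagate_shapes(arch)
    expect_true(all(tb$feasible))
    expect_true(all(tb$out_h >= 1 & tb$out_w >= 1))
  }
})

test_that("feasibility check enforces both budgets and reports violations", {
  arch <- tiny_arch(8, 2, filters = 16)
  small <- feasibility_check(arch, list(max_parameters = 10,
                                        max_activation_cells = 1e7))
  expect_false(small$pass)
  expect_identical(small$violated, "max_parameters")
  cells <- feasibility_check(arch, list(max_parameters = 1e7,
                                        max_activation_cells = 10))
  expect_identical(cells$violated, "max_activation_cells")
  bare <- architecture_spec(c(8, 8, 3), list(), 2)
  expect_true(feasibility_check(bare, list(max_parameters = 1000,
                                           max_activation_cells = 1000))$pass)
  ref <- cnn224_5_40()
  # 10M-parameter budget admits the 4.47M-parameter reference model; its
  # peak activation map is 224 x 224 x 261 ~ 13.1M cells
  expect_true(feasibility_check(ref$arch,
                                list(max_parameters = 1e7,
                                     max_activation_cells = 2e7))$pass)
})

test_that("parameter counting matches closed-form layer arithmetic", {
  a <- architecture_spec(c(8, 8, 3), list(
    list(type = "conv", filter_size = 1, num_filters = 87, stride = 1)), 7)
  pt <- count_parameters(a)
  expect_equal(pt$parameters[1], 1 * 3 * 87 + 87)  # 348
  # classifier-only model over an 84-channel input: 84*7+7
  bare <- architecture_spec(c(1, 1, 84), list(), 7)
  expect_equal(attr(count_parameters(bare), "total"), 595)
})

test_that("FLOP accounting is linear in filter count with documented convention", {
  unit <- architecture_spec(c(1, 1, 1), list(
    list(type = "conv", filter_size = 1, num_filters = 1, stride = 1)), 2)
  ft <- count_flops(unit)
  expect_equal(ft$flops[1], 2)
  one <- architecture_spec(c(8, 8, 3), list(
    list(type = "conv", filter_size = 3, num_filters = 16, stride = 1)), 2)
  two <- architecture_spec(c(8, 8, 3), list(
    list(type = "conv", filter_size = 3, num_filters = 32, stride = 1)), 2)
  expect_equal(2 * count_flops(one)$flops[1], count_flops(two)$flops[1])
  expect_match(attr(ft, "convention"), "fs\\^2")
})

test_that("architecture documents round-trip through JSON", {
  ref <- cnn224_5_40()
  doc <- serialize_architecture(ref$arch)
  back <- deserialize_architecture(doc)
  expect_identical(back$layers, ref$arch$layers)
  expect_identical(back$input_shape, ref$arch$input_shape)
  expect_identical(back$num_classes, ref$arch$num_classes)
  expect_error(deserialize_architecture('{"input_shape": [8, 8, 3]}'),
               "num_classes")
  hand <- '{
    "schema": "sadasnet-architecture/1",
    "input_shape": [8, 8, 3], "num_classes": 2,
    "layers": [
      {"type": "conv", "filter_size": 3, "num_filters": 4, "stride": 1},
      {"type": "pool", "pool_type": "max", "filter_size": 2, "stride": 2}
    ]}'
  parsed <- deserialize_architecture(hand)
  built <- architecture_spec(c(8, 8, 3), list(
    list(type = "conv", filter_size = 3L, num_filters = 4L, stride = 1L),
    list(type = "pool", pool_type = "max", filter_size = 2L, stride = 2L)),
    2)
  expect_equal(parsed$layers, built$layers)
})

test_that("file round trip preserves the reference model", {
  ref <- cnn224_5_40()
  path <- withr::local_tempfile(fileext = ".json")
  serialize_architecture(ref$arch, path, provenance = list(seed = 1))
  back <- deserialize_architecture(path)
  expect_identical(back$layers, ref$arch$layers)
})
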