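# Architecture decoding, shape propagation, repair, hardware-budget
# feasibility, and parameter/FLOP accounting.
#
# Conventions (documented in the methods vignette):
#  * serial and multi-branch convolutions use SAME zero padding, so the
#    output spatial extent is ceil(in / stride); every convolution carries
#    biases and is followed by ReLU, with no normalization layers;
#  * branch i of a multi-branch block uses kernel 2i - 1 (1, 3, 5, 7),
#    stride 1, and all branches are concatenated channel-wise;
#  * pooling uses VALID padding: floor((in - fs) / stride) + 1;
#  * the classifier head is global average pooling -> (optional hidden FC
#    layers) -> FC to num_classes -> softmax.

#' Decode a genome into an architecture
#'
#' Walks the genome slot by slot. In each macro slot the convolution control
#' gene selects a serial convolution (control = 1) or a multi-branch block
#' (control = 2); the pooling control gene (0/1) decides whether a pooling
#' layer follows. Each fully connected slot's control gene (0/1) decides
#' whether a hidden FC layer is appended. A classifier head (global average
#' pooling, an FC layer to `num_classes`, softmax) is always implied and is
#' not part of the layer list. The multi-branch filter-size gene is decoded
#' and stored (`decoded_filter_size`) but the branch kernels are fixed at
#' 1/3/5/7; see the methods vignette.
#'
#' @param genome Numeric vector in `[0, 1]` of length `layout$D`.
#' @param layout A [build_layout()] result.
#' @param input_shape Integer vector `c(height, width, channels)`.
#' @param num_classes Number of output classes, `>= 2`.
#' @return Object of class `arch_spec` with fields `input_shape`, `layers`
#'   (ordered tagged list: `conv`, `multibranch`, `pool`, `fc`) and
#'   `num_classes`.
#' @export
decode_architecture <- function(genome, layout, input_shape, num_classes) {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(genome) != layout$D)
    stop("decode error: genome length ", length(genome),
         " does not match layout D = ", layout$D, call. = FALSE)
  if (num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  gm <- layout$gene_map
  rg <- layout$config$ranges
  val <- function(slot_type, s, gene) {
    i <- which(gm$slot_type == slot_type & gm$slot == s & gm$gene == gene)
    denormalize_gene(genome[i], rg[[gene]])
  }
  layers <- list()
  for (s in seq_len(layout$config$max_macro_layers)) {
    cc <- val("macro", s, "conv_control")
    if (cc == 1) {
      layers[[length(layers) + 1]] <- list(
        type = "conv",
        filter_size = val("macro", s, "conv_fs"),
        num_filters = val("macro", s, "conv_nf"),
        stride = val("macro", s, "conv_stride"))
    } else {
      nb <- val("macro", s, "mb_nb")
      layers[[length(layers) + 1]] <- list(
        type = "multibranch",
        num_branches = nb,
        filters_per_branch = val("macro", s, "mb_nf"),
        branch_kernels = 2L * seq_len(nb) - 1L,
        decoded_filter_size = val("macro", s, "mb_fs"))
    }
    if (val("macro", s, "pool_control") == 1) {
      layers[[length(layers) + 1]] <- list(
        type = "pool",
        pool_type = c("max", "avg")[val("macro", s, "pool_type")],
        filter_size = val("macro", s, "pool_fs"),
        stride = val("macro", s, "pool_stride"))
    }
  }
  for (s in seq_len(layout$config$fc_slots)) {
    if (val("fc", s, "fc_control") == 1) {
      layers[[length(layers) + 1]] <- list(
        type = "fc", num_neurons = val("fc", s, "fc_nn"))
    }
  }
  architecture_spec(input_shape, layers, num_classes)
}

#' Construct an architecture specification directly
#'
#' @param input_shape Integer vector `c(height, width, channels)`.
#' @param layers Ordered list of tagged layer entries as produced by
#'   [decode_architecture()]; may be empty (classifier-only model).
#' @param num_classes Number of output classes, `>= 2`.
#' @return Object of class `arch_spec`.
#' @export
architecture_spec <- function(input_shape, layers, num_classes) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape < 1))
    stop("input_shape must be c(height, width, channels), all >= 1",
         call. = FALSE)
  if (num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  seen_fc <- FALSE
  for (ly in layers) {
    if (!is.list(ly) || is.null(ly$type) ||
        !ly$type %in% c("conv", "multibranch", "pool", "fc"))
      stop("layers must be tagged conv/multibranch/pool/fc entries",
           call. = FALSE)
    if (ly$type == "fc") seen_fc <- TRUE
    else if (seen_fc)
      stop("feature layers cannot follow fully connected layers",
           call. = FALSE)
  }
  structure(list(input_shape = input_shape, layers = layers,
                 num_classes = as.integer(num_classes)),
            class = "arch_spec")
}

# Channels produced by a feature layer given input channels.
.layer_out_channels <- function(ly, cin) {
  switch(ly$type,
         conv = ly$num_filters,
         multibranch = ly$num_branches * ly$filters_per_branch,
         pool = cin,
         stop("not a feature layer"))
}

.layer_label <- function(ly) {
  switch(ly$type,
         conv = sprintf("conv %dx%d, %d filters, stride %d",
                        ly$filter_size, ly$filter_size, ly$num_filters,
                        ly$stride),
         multibranch = sprintf("multibranch x%d, %d filters/branch",
                               ly$num_branches, ly$filters_per_branch),
         pool = sprintf("%s pool %dx%d, stride %d", ly$pool_type,
                        ly$filter_size, ly$filter_size, ly$stride),
         fc = sprintf("fc, %d neurons", ly$num_neurons))
}

#' Propagate feature-map shapes through an architecture
#'
#' Serial and multi-branch convolutions use SAME padding (output spatial
#' extent `ceil(in / stride)`); pooling uses VALID padding
#' (`floor((in - fs) / stride) + 1`). A pooling layer whose filter exceeds
#' the current spatial extent is flagged infeasible (consumed by
#' [repair_architecture()]). Multi-branch output channels are
#' `num_branches * filters_per_branch`; branch spatial dims always agree
#' since branches use stride 1 and SAME padding.
#'
#' @param arch An `arch_spec`.
#' @return Data frame with one row per layer plus the implied global-pool
#'   and classifier rows: columns `index`, `type`, `layer`, `out_h`,
#'   `out_w`, `out_c`, `feasible`.
#' @export
propagate_shapes <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  h <- arch$input_shape[1]; w <- arch$input_shape[2]
  c <- arch$input_shape[3]
  rows <- list()
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    feasible <- TRUE
    if (ly$type %in% c("conv", "multibranch")) {
      s <- if (ly$type == "conv") ly$stride else 1L
      h <- ceiling(h / s); w <- ceiling(w / s)
      c <- .layer_out_channels(ly, c)
    } else if (ly$type == "pool") {
      if (ly$filter_size > min(h, w)) {
        feasible <- FALSE   # window larger than the map: shapes unchanged
      } else {
        h <- floor((h - ly$filter_size) / ly$stride) + 1
        w <- floor((w - ly$filter_size) / ly$stride) + 1
      }
    } else {  # fc
      h <- 1; w <- 1
      c <- ly$num_neurons
    }
    rows[[i]] <- data.frame(index = i, type = ly$type,
                            layer = .layer_label(ly),
                            out_h = h, out_w = w, out_c = c,
                            feasible = feasible, stringsAsFactors = FALSE)
  }
  n <- length(rows)
  first_fc <- which(vapply(arch$layers, function(l) l$type == "fc",
                           logical(1)))
  # the implied head: global average pooling happens before any fc layer
  gap_c <- if (length(first_fc)) {
    if (first_fc[1] == 1) arch$input_shape[3] else rows[[first_fc[1] - 1]]$out_c
  } else c
  rows[[n + 1]] <- data.frame(index = n + 1, type = "gap",
                              layer = "global average pool",
                              out_h = 1, out_w = 1, out_c = gap_c,
                              feasible = TRUE, stringsAsFactors = FALSE)
  rows[[n + 2]] <- data.frame(index = n + 2, type = "output",
                              layer = sprintf("fc, %d classes (softmax)",
                                              arch$num_classes),
                              out_h = 1, out_w = 1, out_c = arch$num_classes,
                              feasible = TRUE, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "input_shape") <- arch$input_shape
  out
}

#' Remove layers that cannot be applied to the current feature map
#'
#' Scans the layers in order; whenever shape propagation flags a layer
#' infeasible (a pooling window larger than the remaining spatial extent),
#' that layer is removed and propagation resumes. The result always passes
#' [propagate_shapes()] with all spatial dims `>= 1`; an architecture
#' reduced to the classifier head alone is still valid. Removals are
#' recorded in `attr(, "repair_log")`. Idempotent.
#'
#' @param arch An `arch_spec`.
#' @return The repaired `arch_spec`.
#' @export
repair_architecture <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  log <- attr(arch, "repair_log") %||% character(0)
  repeat {
    tb <- propagate_shapes(arch)
    bad <- which(!tb$feasible)
    if (!length(bad)) break
    i <- bad[1]
    log <- c(log, sprintf("removed layer %d (%s)", i, tb$layer[i]))
    arch$layers[[i]] <- NULL
  }
  attr(arch, "repair_log") <- log
  arch
}

# Full shape trace used by the counters: per printed-style row (multibranch
# expanded to one row per branch), with input channels, output shape,
# kernel, stride, filters and learnable parameter count.
.param_rows <- function(arch) {
  tb <- propagate_shapes(arch)
  if (any(!tb$feasible))
    stop("architecture has infeasible layers; run repair_architecture() first",
         call. = FALSE)
  h <- arch$input_shape[1]; w <- arch$input_shape[2]
  cin <- arch$input_shape[3]
  rows <- list()
  add <- function(layer, type, out_h, out_w, out_c, filters, kernel, stride,
                  params, flops) {
    rows[[length(rows) + 1]] <<- data.frame(
      layer = layer, type = type, out_h = out_h, out_w = out_w,
      out_c = out_c, filters = filters, kernel = kernel, stride = stride,
      parameters = params, flops = flops, stringsAsFactors = FALSE)
  }
  feat_c <- cin
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      oh <- ceiling(h / ly$stride); ow <- ceiling(w / ly$stride)
      p <- ly$filter_size^2 * feat_c * ly$num_filters + ly$num_filters
      f <- 2 * ly$filter_size^2 * feat_c * ly$num_filters * oh * ow
      add(.layer_label(ly), "conv", oh, ow, ly$num_filters, ly$num_filters,
          sprintf("%dx%d", ly$filter_size, ly$filter_size), ly$stride, p, f)
      h <- oh; w <- ow; feat_c <- ly$num_filters
    } else if (ly$type == "multibranch") {
      for (b in seq_len(ly$num_branches)) {
        k <- ly$branch_kernels[b]
        p <- k^2 * feat_c * ly$filters_per_branch + ly$filters_per_branch
        f <- 2 * k^2 * feat_c * ly$filters_per_branch * h * w
        add(sprintf("multibranch %d/%d (%dx%d)", b, ly$num_branches, k, k),
            "conv_branch", h, w, ly$filters_per_branch,
            ly$filters_per_branch, sprintf("%dx%d", k, k), 1L, p, f)
      }
      feat_c <- ly$num_branches * ly$filters_per_branch
    } else if (ly$type == "pool") {
      h <- floor((h - ly$filter_size) / ly$stride) + 1
      w <- floor((w - ly$filter_size) / ly$stride) + 1
      add(.layer_label(ly), "pool", h, w, feat_c, NA_integer_,
          sprintf("%dx%d", ly$filter_size, ly$filter_size), ly$stride, 0, 0)
    } else {  # hidden fc: first one consumes the globally pooled features
      if (h != 1 || w != 1) { h <- 1; w <- 1 }
      p <- feat_c * ly$num_neurons + ly$num_neurons
      f <- 2 * feat_c * ly$num_neurons
      add(.layer_label(ly), "fc", 1L, 1L, ly$num_neurons, NA_integer_, "1x1",
          1L, p, f)
      feat_c <- ly$num_neurons
    }
  }
  k <- arch$num_classes
  add(sprintf("fc, %d classes (softmax)", k), "output", 1L, 1L, k,
      NA_integer_, "1x1", 1L, feat_c * k + k, 2 * feat_c * k)
  out <- do.call(rbind, rows)
  out <- cbind(no = seq_len(nrow(out)), out)
  out
}

#' Count learnable parameters per layer
#'
#' Convolutions count `fs^2 * c_in * n_filters + n_filters` (weights plus
#' biases); each multi-branch branch is counted as a convolution with its
#' own kernel; pooling layers carry no parameters; a fully connected layer
#' with `n` inputs and `m` outputs counts `n * m + m`. The final classifier
#' receives the globally pooled `1 x 1 x C` feature map. No normalization
#' parameters exist in this family.
#'
#' @param arch A repaired `arch_spec`.
#' @return Data frame of per-layer rows (multi-branch blocks expanded to
#'   one row per branch, classifier included) with a `parameters` column;
#'   `attr(, "total")` holds the total count.
#' @export
count_parameters <- function(arch) {
  rows <- .param_rows(arch)
  out <- rows[, c("no", "layer", "type", "out_h", "out_w", "out_c",
                  "filters", "kernel", "stride", "parameters")]
  attr(out, "total") <- sum(rows$parameters)
  out
}

#' Count multiply-add FLOPs per layer
#'
#' Convention: a convolution producing an `H x W` map with `n` filters of
#' size `fs` over `c` input channels costs `2 * fs^2 * c * n * H * W` FLOPs
#' (one multiply and one add per MAC); a fully connected layer costs
#' `2 * n_in * n_out`; pooling and global pooling are counted as zero. The
#' convention is recorded in `attr(, "convention")`.
#'
#' @param arch A repaired `arch_spec`.
#' @return Data frame of per-layer rows with a `flops` column;
#'   `attr(, "total")` holds the total.
#' @export
count_flops <- function(arch) {
  rows <- .param_rows(arch)
  out <- rows[, c("no", "layer", "type", "out_h", "out_w", "out_c",
                  "kernel", "stride", "flops")]
  attr(out, "total") <- sum(rows$flops)
  attr(out, "convention") <-
    "2*fs^2*Cin*Cout*Hout*Wout per conv; 2*Cin*Cout per FC; pooling = 0"
  out
}

#' Total learnable parameters of an architecture
#' @param arch A repaired `arch_spec`.
#' @return Integer-valued scalar.
#' @export
total_parameters <- function(arch) attr(count_parameters(arch), "total")

#' Hardware-budget feasibility check
#'
#' Proxies the "fits on the accelerator" test with two hardware-independent
#' budgets: total learnable parameters and the peak activation cell count
#' (the largest `H * W * C` over the input and every layer output).
#' Candidates that fail are not trained; the search assigns them worst-case
#' fitness.
#'
#' @param arch A repaired `arch_spec`.
#' @param budget List with `max_parameters` and `max_activation_cells`.
#' @return List: `pass` (logical), `total_parameters`,
#'   `peak_activation_cells`, `violated` (character, possibly empty).
#' @export
feasibility_check <- function(arch,
                              budget = list(max_parameters = 2e7,
                                            max_activation_cells = 5e7)) {
  tp <- total_parameters(arch)
  tb <- propagate_shapes(arch)
  cells <- c(prod(arch$input_shape), tb$out_h * tb$out_w * tb$out_c)
  peak <- max(cells)
  violated <- character(0)
  if (tp > budget$max_parameters) violated <- c(violated, "max_parameters")
  if (peak > budget$max_activation_cells)
    violated <- c(violated, "max_activation_cells")
  list(pass = length(violated) == 0, total_parameters = tp,
       peak_activation_cells = peak, violated = violated)
}

#' Serialize an architecture to a JSON document
#'
#' The document is schema-versioned and human-readable; it embeds the layer
#' list, input shape, class count, the derived shape/parameter table, and
#' optional decode provenance.
#'
#' @param arch An `arch_spec`.
#' @param path Optional file path; when given the JSON is written there.
#' @param provenance Optional named list (e.g. genome hash, seed) stored
#'   verbatim.
#' @return The JSON string, invisibly when `path` is given.
#' @export
serialize_architecture <- function(arch, path = NULL, provenance = NULL) {
  stopifnot(inherits(arch, "arch_spec"))
  doc <- list(schema = "sadasnet-architecture/1",
              input_shape = arch$input_shape,
              num_classes = arch$num_classes,
              layers = arch$layers)
  repaired <- tryCatch(propagate_shapes(arch), error = function(e) NULL)
  if (!is.null(repaired) && all(repaired$feasible)) {
    pt <- count_parameters(arch)
    doc$derived <- list(parameter_table = pt,
                        total_parameters = attr(pt, "total"),
                        total_flops = attr(count_flops(arch), "total"))
  }
  if (!is.null(provenance)) doc$provenance <- provenance
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read an architecture back from a JSON document
#'
#' @param input JSON string or path to a JSON file.
#' @return The reconstructed `arch_spec`; derived tables are recomputed, not
#'   trusted from the document.
#' @export
deserialize_architecture <- function(input) {
  txt <- if (length(input) == 1 && file.exists(input))
    paste(readLines(input, warn = FALSE), collapse = "\n") else input
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyDataFrame = FALSE,
                                     simplifyVector = TRUE),
                  error = function(e)
                    stop("parse error in architecture document: ",
                         conditionMessage(e), call. = FALSE))
  for (field in c("input_shape", "num_classes", "layers"))
    if (is.null(doc[[field]]))
      stop("parse error: architecture document lacks '", field, "'",
           call. = FALSE)
  layers <- lapply(doc$layers, function(ly) {
    ly <- as.list(ly)
    for (f in c("filter_size", "num_filters", "stride", "num_branches",
                "filters_per_branch", "branch_kernels",
                "decoded_filter_size", "num_neurons"))
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    ly
  })
  architecture_spec(doc$input_shape, layers, doc$num_classes)
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> input %dx%dx%d, %d classes, %d layer(s) + head\n",
              x$input_shape[1], x$input_shape[2], x$input_shape[3],
              x$num_classes, length(x$layers)))
  tb <- tryCatch(propagate_shapes(x), error = function(e) NULL)
  if (!is.null(tb) && all(tb$feasible)) {
    pt <- count_parameters(x)
    print(pt, row.names = FALSE)
    cat("total parameters:", format(attr(pt, "total"), big.mark = ","), "\n")
  } else {
    for (i in seq_along(x$layers)) cat(" ", i, .layer_label(x$layers[[i]]), "\n")
    if (!is.null(tb)) cat("  (contains infeasible layers; repair first)\n")
  }
  invisible(x)
}

#' The published best 224x224 dermoscopy model (CNN224_5_40)
#'
#' Reconstructs the CNN224_5_40 architecture -- the best model found by the
#' 5-particle x 40-iteration search at 224 x 224 x 3 -- by inverse-mapping
#' its per-layer hyperparameters through [normalize_value()] into a genome
#' and decoding it. The model alternates multi-branch blocks (3 x 87,
#' 4 x 102, 3 x 41, 3 x 28 filters) and serial 6 x 6 stride-2 convolutions
#' (112, 144 filters) with max-pooling, ending in the global-pool classifier
#' over 84 concatenated channels and 7 lesion classes.
#'
#' @return List with `genome`, `layout` and the decoded `arch` (repaired).
#' @export
cnn224_5_40 <- function() {
  config <- search_space_config(max_macro_layers = 6, fc_slots = 1)
  layout <- build_layout(config)
  rg <- config$ranges
  g <- numeric(layout$D)
  gm <- layout$gene_map
  set_gene <- function(slot_type, s, gene, value) {
    i <- which(gm$slot_type == slot_type & gm$slot == s & gm$gene == gene)
    g[i] <<- normalize_value(value, rg[[gene]])
  }
  mb <- function(s, nb, nf) {
    set_gene("macro", s, "conv_control", 2)
    set_gene("macro", s, "mb_nb", nb)
    set_gene("macro", s, "mb_nf", nf)
    set_gene("macro", s, "mb_fs", 2)       # decoded but unused
  }
  conv <- function(s, fs, nf, stride) {
    set_gene("macro", s, "conv_control", 1)
    set_gene("macro", s, "conv_fs", fs)
    set_gene("macro", s, "conv_nf", nf)
    set_gene("macro", s, "conv_stride", stride)
  }
  pool <- function(s, fs, stride) {
    set_gene("macro", s, "pool_control", 1)
    set_gene("macro", s, "pool_type", 1)   # max
    set_gene("macro", s, "pool_fs", fs)
    set_gene("macro", s, "pool_stride", stride)
  }
  mb(1, 3, 87);           pool(1, 1, 2)
  conv(2, 6, 112, 2);     pool(2, 4, 2)
  mb(3, 4, 102);          pool(3, 4, 2)
  conv(4, 6, 144, 2);     pool(4, 4, 2)
  mb(5, 3, 41)            # pool_control stays 0
  mb(6, 3, 28)
  # fc_control stays 0: no hidden FC before the classifier
  arch <- repair_architecture(
    decode_architecture(g, layout, c(224, 224, 3), 7))
  list(genome = g, layout = layout, arch = arch)
}
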