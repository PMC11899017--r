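# Search space: bounded hyperparameter ranges, the fixed-length genome
# layout, and the normalize/denormalize mapping between continuous particle
# positions and discrete layer hyperparameters.

#' Integer hyperparameter range
#'
#' A closed integer interval `[lower, upper]` for one architectural
#' hyperparameter, tagged with the role it plays during decoding.
#'
#' @param name Short identifier (e.g. `"conv_nf"`).
#' @param lower,upper Inclusive integer bounds, `lower <= upper`.
#' @param role One of `"conv_control"`, `"branch_count"`, `"filter_size"`,
#'   `"filter_count"`, `"stride"`, `"pool_control"`, `"pool_type"`,
#'   `"fc_control"`, `"neuron_count"`.
#' @return An object of class `param_range`.
#' @export
param_range <- function(name, lower, upper, role) {
  roles <- c("conv_control", "branch_count", "filter_size", "filter_count",
             "stride", "pool_control", "pool_type", "fc_control",
             "neuron_count")
  role <- match.arg(role, roles)
  if (lower != as.integer(lower) || upper != as.integer(upper))
    stop("range '", name, "': bounds must be integers", call. = FALSE)
  if (lower > upper)
    stop("invalid range '", name, "': lower (", lower,
         ") exceeds upper (", upper, ")", call. = FALSE)
  structure(list(name = name, lower = as.integer(lower),
                 upper = as.integer(upper), role = role),
            class = "param_range")
}

#' Default hyperparameter ranges of the search space
#'
#' Standard (serial) convolutions: control in `[1, 2]` (1 = serial,
#' 2 = multi-branch), filter size `[2, 8]`, filter count `[8, 512]`,
#' stride `[1, 3]`. Multi-branch convolutions: branch count `[2, 4]`,
#' filter size `[2, 8]`, filters per branch `[4, 128]`. Pooling: presence
#' control `[0, 1]`, type `[1, 2]` (1 = max, 2 = average), filter size
#' `[1, 7]`, stride `[1, 3]`. Fully connected: presence control `[0, 1]`,
#' neuron count `[10, 512]`.
#'
#' @return Named list of [param_range()] objects.
#' @export
default_ranges <- function() {
  list(
    conv_control = param_range("conv_control", 1, 2, "conv_control"),
    conv_fs      = param_range("conv_fs", 2, 8, "filter_size"),
    conv_nf      = param_range("conv_nf", 8, 512, "filter_count"),
    conv_stride  = param_range("conv_stride", 1, 3, "stride"),
    mb_nb        = param_range("mb_nb", 2, 4, "branch_count"),
    mb_fs        = param_range("mb_fs", 2, 8, "filter_size"),
    mb_nf        = param_range("mb_nf", 4, 128, "filter_count"),
    pool_control = param_range("pool_control", 0, 1, "pool_control"),
    pool_type    = param_range("pool_type", 1, 2, "pool_type"),
    pool_fs      = param_range("pool_fs", 1, 7, "filter_size"),
    pool_stride  = param_range("pool_stride", 1, 3, "stride"),
    fc_control   = param_range("fc_control", 0, 1, "fc_control"),
    fc_nn        = param_range("fc_nn", 10, 512, "neuron_count")
  )
}

#' Search-space configuration
#'
#' @param max_macro_layers Number of candidate feature-extraction slots.
#'   Each slot carries one convolution gene group (serial or multi-branch,
#'   chosen by its control gene) and one optional pooling gene group.
#' @param fc_slots Number of candidate fully connected slots.
#' @param ranges Named list of [param_range()] overrides; unnamed entries of
#'   [default_ranges()] are kept.
#' @return Object of class `search_space_config`.
#' @export
search_space_config <- function(max_macro_layers = 13, fc_slots = 1,
                                ranges = list()) {
  if (max_macro_layers < 1)
    stop("configuration error: max_macro_layers must be >= 1", call. = FALSE)
  if (fc_slots < 0)
    stop("configuration error: fc_slots must be >= 0", call. = FALSE)
  rg <- default_ranges()
  for (nm in names(ranges)) {
    if (!nm %in% names(rg))
      stop("configuration error: unknown range '", nm, "'", call. = FALSE)
    ov <- ranges[[nm]]
    if (!inherits(ov, "param_range"))
      ov <- param_range(nm, ov[[1]], ov[[2]], rg[[nm]]$role)
    rg[[nm]] <- ov
  }
  structure(list(max_macro_layers = as.integer(max_macro_layers),
                 fc_slots = as.integer(fc_slots), ranges = rg),
            class = "search_space_config")
}

# Gene names of one macro (feature-extraction) slot, in genome order.
# Exactly one control gene governs the convolution group and one governs
# the pooling group.
.macro_genes <- c("conv_control", "conv_fs", "conv_nf", "conv_stride",
                  "mb_nb", "mb_fs", "mb_nf",
                  "pool_control", "pool_type", "pool_fs", "pool_stride")
.fc_genes <- c("fc_control", "fc_nn")

#' Build the fixed-length genome layout
#'
#' Lays out one contiguous gene group per macro slot -- the serial-conv
#' genes, the multi-branch genes and the pooling genes, each guarded by a
#' control gene -- followed by one `{control, neurons}` group per fully
#' connected slot. Unused genes (e.g. the serial-conv genes of a slot whose
#' control selects the multi-branch variant) travel silently, which keeps
#' the dimensionality fixed for the swarm.
#'
#' @param config A [search_space_config()].
#' @return Object of class `genome_layout` with elements `config`,
#'   `gene_map` (data frame: gene index, slot, slot type, gene name, bounds,
#'   role) and `D` (total genome length).
#' @export
build_layout <- function(config = search_space_config()) {
  if (!inherits(config, "search_space_config"))
    stop("config must be a search_space_config", call. = FALSE)
  rows <- list()
  for (s in seq_len(config$max_macro_layers)) {
    for (g in .macro_genes) {
      r <- config$ranges[[g]]
      rows[[length(rows) + 1]] <- data.frame(
        slot = s, slot_type = "macro", gene = g,
        lower = r$lower, upper = r$upper, role = r$role,
        stringsAsFactors = FALSE)
    }
  }
  for (s in seq_len(config$fc_slots)) {
    for (g in .fc_genes) {
      r <- config$ranges[[g]]
      rows[[length(rows) + 1]] <- data.frame(
        slot = s, slot_type = "fc", gene = g,
        lower = r$lower, upper = r$upper, role = r$role,
        stringsAsFactors = FALSE)
    }
  }
  gene_map <- do.call(rbind, rows)
  gene_map$index <- seq_len(nrow(gene_map))
  structure(list(config = config, gene_map = gene_map, D = nrow(gene_map)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> D =", x$D, "genes:",
      x$config$max_macro_layers, "macro slot(s) x", length(.macro_genes),
      "genes +", x$config$fc_slots, "fc slot(s) x", length(.fc_genes),
      "genes\n")
  invisible(x)
}

#' Denormalize one gene to its integer hyperparameter
#'
#' Maps a normalized coordinate `p` in `[0, 1]` to the integer
#' `round(lower + (upper - lower) * p)` (half away from zero), attaining
#' `lower` at `p = 0` and `upper` at `p = 1` and nondecreasing in between.
#'
#' @param p Real in `[0, 1]` (vectorized).
#' @param range A [param_range()].
#' @return Integer vector in `[lower, upper]`.
#' @export
denormalize_gene <- function(p, range) {
  stopifnot(inherits(range, "param_range"))
  if (any(p < 0 | p > 1))
    stop("domain error: normalized value outside [0, 1] for range '",
         range$name, "' (callers must clamp first)", call. = FALSE)
  as.integer(round_half_away(range$lower + (range$upper - range$lower) * p))
}

#' Normalize an integer hyperparameter to `[0, 1]`
#'
#' Inverse of [denormalize_gene()]: `(v - lower) / (upper - lower)`. The
#' round trip `denormalize_gene(normalize_value(v, r), r) == v` holds for
#' every integer `v` in the range. Degenerate ranges (`lower == upper`)
#' map to 0.
#'
#' @param v Integer in `[lower, upper]`.
#' @param range A [param_range()].
#' @return Real in `[0, 1]`.
#' @export
normalize_value <- function(v, range) {
  stopifnot(inherits(range, "param_range"))
  if (any(v < range$lower | v > range$upper))
    stop("domain error: value ", v[v < range$lower | v > range$upper][1],
         " outside range '", range$name, "' [", range$lower, ", ",
         range$upper, "]", call. = FALSE)
  if (range$upper == range$lower) return(rep(0, length(v)))
  (v - range$lower) / (range$upper - range$lower)
}

#' Sample a random genome
#'
#' Draws every gene independently from U(0, 1) using the current RNG state
#' (or a temporary state when `seed` is given).
#'
#' @param layout A [build_layout()] result.
#' @param seed Optional integer; when given the caller's RNG is untouched.
#' @return Numeric vector of length `layout$D`, all entries in `[0, 1]`.
#' @export
random_genome <- function(layout, seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.null(seed)) runif(layout$D) else local_seed(seed, runif(layout$D))
}
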