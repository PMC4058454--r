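# Hierarchical extraction and mergence. Any intensity section of a region
# can itself be re-partitioned by local multilevel Otsu (the application
# domain shrinks, so minor patches emerge), written as dotted class paths:
# "3.1" is the dark sub-section of the bright section. Layers are combined
# by a small algebra — union, interior holes, watershed — and merged into
# the raw segmentation result. Recursion is capped at depth 3: deeper
# digging yields no usable patches.

MAX_PATH_DEPTH <- 3L

#' Parse a combination-strategy expression
#'
#' Grammar: `sel(PATH[@LAYER]) | union(E, E, ...) | holes(E) | ws(E)` where
#' `PATH` is a dotted sequence of class ids in 1..4 (at most 3 deep) and the
#' optional `@LAYER` names the reference layer read by the re-partition at
#' the deepest level of that path. Example: the composite strategy
#' `"union(sel(1), holes(union(sel(3.3), sel(3.4))), sel(3.1),
#' holes(union(sel(4.3), sel(4.4))), sel(4.1), sel(4.2))"` merges the dark
#' section, the interior holes of the bright/prone-bright sub-sections of
#' the bright sections, and the dark sub-sections of the bright sections.
#'
#' @param text Strategy expression string.
#' @return An object of class `hma_strategy` (an expression tree).
#' @export
parse_strategy <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- gsub("[[:space:]]+", "", text)
  pos <- 1L
  peek <- function() if (pos <= nchar(src)) substr(src, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  fail <- function(msg) stop("strategy parse error at position ", pos, ": ",
                             msg, " in '", text, "'", call. = FALSE)
  expect <- function(ch) {
    if (peek() != ch) fail(paste0("expected '", ch, "'"))
    advance()
  }
  read_word <- function() {
    start <- pos
    while (grepl("[a-zA-Z0-9_.]", peek())) advance()
    if (pos == start) fail("expected a name")
    substr(src, start, pos - 1L)
  }
  parse_expr <- function() {
    word <- read_word()
    expect("(")
    node <- switch(word,
      sel = {
        start <- pos
        while (grepl("[0-9.]", peek())) advance()
        path_txt <- substr(src, start, pos - 1L)
        layer <- NULL
        if (peek() == "@") {
          advance()
          layer <- read_word()
        }
        path <- suppressWarnings(as.integer(strsplit(path_txt, ".", fixed = TRUE)[[1]]))
        if (length(path) == 0L || anyNA(path)) fail("invalid class path")
        if (length(path) > MAX_PATH_DEPTH)
          fail(paste0("class path deeper than ", MAX_PATH_DEPTH))
        if (!all(path %in% 1:4)) fail("class ids must be in 1..4")
        list(kind = "sel", path = path, layer = layer)
      },
      union = {
        children <- list(parse_expr())
        while (peek() == ",") {
          advance()
          children[[length(children) + 1L]] <- parse_expr()
        }
        list(kind = "union", children = children)
      },
      holes = list(kind = "holes", child = parse_expr()),
      ws = list(kind = "ws", child = parse_expr()),
      fail(paste0("unknown operator '", word, "'"))
    )
    expect(")")
    node
  }
  tree <- parse_expr()
  if (pos <= nchar(src)) fail("trailing input")
  structure(tree, class = "hma_strategy")
}

#' @rdname parse_strategy
#' @param expr An `hma_strategy` tree.
#' @return `format_strategy` returns the normalized string form.
#' @export
format_strategy <- function(expr) {
  fmt <- function(node) {
    switch(node$kind,
      sel = paste0("sel(", paste(node$path, collapse = "."),
                   if (!is.null(node$layer)) paste0("@", node$layer) else "", ")"),
      union = paste0("union(", paste(vapply(node$children, fmt, ""),
                                     collapse = ", "), ")"),
      holes = paste0("holes(", fmt(node$child), ")"),
      ws = paste0("ws(", fmt(node$child), ")"))
  }
  fmt(expr)
}

#' @exportS3Method base::print
print.hma_strategy <- function(x, ...) {
  cat(format_strategy(x), "\n")
  invisible(x)
}

#' Interior holes of a binary mask
#'
#' Returns the union of the 4-connected background components that do not
#' touch the image border — the areas fully enclosed by the mask. Hole
#' layers matter because the bright halo sections form closed rings around
#' cell interiors: the ring's holes are the cells.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of hole pixels.
#' @export
extract_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  bg <- !mask
  lab <- label_mask(bg, 4L)
  if (max(lab) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_ids <- border_ids[border_ids > 0L]
  hole <- bg & !(lab %in% border_ids)
  matrix(hole, nrow(mask), ncol(mask))
}

#' Evaluation context for strategy expressions
#'
#' Bundles the level-1 class map, the reference stack and the ROI, plus a
#' cache of re-partitions so that repeated sub-expressions are evaluated
#' once and reproducibly.
#'
#' @param base_classmap `hma_classmap` of the level-1 partition.
#' @param refstack `hma_refstack` of reference layers.
#' @param roi `hma_roi` mask the base partition was computed on.
#' @param layer_bindings Character vector naming the reference layer read by
#'   re-partitions at depths 2 and 3 (defaults: `graymorph`, then
#'   `original`), overridden per selector by `@LAYER`.
#' @param k Number of thresholds used by re-partitions.
#' @return An object of class `hma_context` (an environment).
#' @export
layer_context <- function(base_classmap, refstack, roi,
                          layer_bindings = c("graymorph", "original"),
                          k = 3L) {
  stopifnot(inherits(base_classmap, "hma_classmap"),
            inherits(refstack, "hma_refstack"))
  ctx <- new.env(parent = emptyenv())
  ctx$base <- base_classmap
  ctx$refstack <- refstack
  ctx$roi <- roi
  ctx$layer_bindings <- layer_bindings
  ctx$k <- k
  ctx$cache <- new.env(parent = emptyenv())
  class(ctx) <- "hma_context"
  ctx
}

# reference layer used when re-partitioning at a given depth (2 or 3)
binding_for_depth <- function(ctx, depth, override = NULL) {
  nm <- if (!is.null(override)) override
        else ctx$layer_bindings[min(depth - 1L, length(ctx$layer_bindings))]
  if (is.null(ctx$refstack[[nm]]))
    stop("unknown reference layer '", nm, "'", call. = FALSE)
  nm
}

#' Re-partition one class of the hierarchy
#'
#' Takes the binary mask of `path` within its parent class map, treats its
#' 8-connected components as new local regions, and classifies them with
#' [local_otsu_classify()] against the named reference layer. Results are
#' cached by `(path, layer)`, so repeated evaluation is bit-identical.
#'
#' @param ctx An `hma_context`.
#' @param path Integer vector of class ids (the parent path).
#' @param layer Reference layer name, or `NULL` for the depth default.
#' @return An `hma_classmap` whose classes partition the `path` mask.
#' @export
repartition <- function(ctx, path, layer = NULL) {
  stopifnot(inherits(ctx, "hma_context"))
  if (length(path) >= MAX_PATH_DEPTH)
    stop("re-partition would exceed the depth limit of ", MAX_PATH_DEPTH,
         call. = FALSE)
  layer <- binding_for_depth(ctx, length(path) + 1L, layer)
  key <- paste0(paste(path, collapse = "."), "@", layer)
  cached <- ctx$cache[[key]]
  if (!is.null(cached)) return(cached)
  parent_mask <- path_mask(ctx, path, layer_chain = NULL)
  regions <- label_mask(parent_mask, 8L)
  cm <- local_otsu_classify(ctx$refstack[[layer]]$image,
                            list(mask = parent_mask, labels = regions),
                            k = ctx$k)
  ctx$cache[[key]] <- cm
  cm
}

# binary mask of a dotted class path; the optional layer override applies
# to the deepest re-partition on the path
path_mask <- function(ctx, path, layer_chain = NULL) {
  if (length(path) == 1L)
    return(class_select(ctx$base, path))
  cm <- repartition(ctx, path[-length(path)], layer = layer_chain)
  class_select(cm, path[length(path)])
}

#' Evaluate a strategy expression to a binary mask
#'
#' Recursive evaluation: `sel` resolves through chained re-partitions,
#' `union` is pixelwise OR, `holes` applies [extract_holes()], and `ws`
#' applies [watershed_split()] and returns the labeled support. The result
#' is always intersected with the ROI mask.
#'
#' @param expr An `hma_strategy` (or a string, parsed on the fly).
#' @param ctx An `hma_context`.
#' @param min_seed_distance Marker separation passed to `ws` nodes.
#' @return Logical matrix.
#' @export
evaluate_strategy <- function(expr, ctx, min_seed_distance = 10) {
  if (is.character(expr)) expr <- parse_strategy(expr)
  stopifnot(inherits(ctx, "hma_context"))
  ev <- function(node) {
    switch(node$kind,
      sel = path_mask(ctx, node$path, layer_chain = node$layer),
      union = Reduce(`|`, lapply(node$children, ev)),
      holes = extract_holes(ev(node$child)),
      ws = watershed_split(ev(node$child), min_seed_distance) > 0L,
      stop("unknown node kind"))
  }
  ev(expr) & ctx$roi$mask
}

# dilate a binary mask without merging its 8-connected components: every
# grown pixel is attributed to its nearest component and pixels where two
# components would meet are left unset (a 1-px divide line)
dilate_preserving_separation <- function(mask, radius) {
  if (!any(mask)) return(mask)
  comp <- label_mask(mask, 8L)
  if (max(comp) == 1L) return(binary_dilate(mask, radius))
  grown <- binary_dilate(mask, radius)
  d <- as.matrix(EBImage::distmap(!mask * 1))
  assigned <- as.matrix(EBImage::propagate(d, seeds = comp, mask = grown))
  storage.mode(assigned) <- "integer"
  divide <- matrix(FALSE, nrow(mask), ncol(mask))
  for (off in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    nb <- shift_replicate(assigned, off[1], off[2])
    divide <- divide | (assigned > 0L & nb > 0L & assigned != nb)
  }
  mask | (grown & assigned > 0L & !divide)
}

#' Expand candidate patches toward the ROI boundary
#'
#' Grows every labeled patch by up to `radius` pixels, restricted to the
#' `within` mask (normally the maximum ROI, so patches never exceed the
#' cell maximum boundary) and without ever merging two labels: contested
#' pixels go to the nearest patch and a 1-px divide line separates
#' neighbors. Extracted patches systematically stop short of the bright
#' halo band; this recovers that margin.
#'
#' @param labels Integer label matrix.
#' @param radius Growth radius in pixels.
#' @param within Logical matrix bounding the growth.
#' @return Integer label matrix with identical label identities.
#' @export
grow_labels <- function(labels, radius, within) {
  if (max(labels, 0L) == 0L || radius <= 0) return(labels)
  sup <- labels > 0L
  grown <- binary_dilate(sup, radius) & within
  d <- as.matrix(EBImage::distmap(!sup * 1))
  asg <- as.matrix(EBImage::propagate(d, seeds = labels, mask = grown))
  storage.mode(asg) <- "integer"
  divide <- matrix(FALSE, nrow(labels), ncol(labels))
  for (off in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    nb <- shift_replicate(asg, off[1], off[2])
    divide <- divide | (asg > 0L & nb > 0L & asg != nb)
  }
  out <- asg
  out[divide & !sup] <- 0L
  out[sup] <- labels[sup]
  out
}

# does the top level of this node derive from a holes() operator?
is_hole_layer <- function(node) {
  identical(node$kind, "holes")
}

#' Merge evaluated layers into the raw segmentation result
#'
#' Hole-derived layers are dilated by a small disk (hollow areas are
#' expanded), layers are merged by OR with overlapping pixels attributed to
#' the earliest layer in the list, the merged mask is clipped to the ROI,
#' and fragments below `min_fragment` pixels are removed.
#'
#' @param layer_masks List of layers, each a list with `expr` (string),
#'   `mask` (logical matrix) and optional `is_hole` flag.
#' @param roi An `hma_roi`.
#' @param dilate_holes Disk radius in pixels applied to hole layers.
#' @param min_fragment Minimum fragment area kept after merging.
#' @param strategy_id Identifier stored with the result.
#' @return An object of class `hma_raw`: list with `mask`,
#'   `contributing_layers` (with per-layer attribution masks) and
#'   `strategy_id`. The mask is always a subset of the ROI mask.
#' @export
merge_to_raw <- function(layer_masks, roi, dilate_holes = 2L,
                         min_fragment = 20L, strategy_id = "strategy") {
  stopifnot(length(layer_masks) >= 1L)
  shape <- dim(layer_masks[[1]]$mask)
  merged <- matrix(FALSE, shape[1], shape[2])
  attribution <- matrix(0L, shape[1], shape[2])
  contributing <- list()
  for (i in seq_along(layer_masks)) {
    lm <- layer_masks[[i]]
    if (!all(dim(lm$mask) == shape)) stop("layer shapes differ", call. = FALSE)
    m <- lm$mask > 0
    if (isTRUE(lm$is_hole) && dilate_holes > 0)
      m <- dilate_preserving_separation(m, dilate_holes) & roi$mask
    new_px <- m & !merged
    attribution[new_px] <- i
    merged <- merged | m
    contributing[[i]] <- list(expr = lm$expr, mask = m, claimed = new_px)
  }
  merged <- merged & roi$mask
  kept <- area_open(merged, min_fragment, 8L)
  attribution[!kept] <- 0L
  structure(list(mask = kept, contributing_layers = contributing,
                 attribution = attribution, strategy_id = strategy_id),
            class = "hma_raw")
}

#' Run the full extraction pipeline for one or more strategies
#'
#' For each strategy string: build (or reuse) the ROI and reference stack,
#' compute the level-1 partition, evaluate every top-level layer of the
#' strategy, and merge layers into a raw result. When a strategy's top node
#' is a `union`, its children are treated as the ordered contributing layers
#' (earlier children win overlaps); otherwise the whole expression is one
#' layer.
#'
#' @param image Numeric matrix in \[0,1\] or an `hma_scene`.
#' @param strategies Character vector of strategy expressions.
#' @param config Configuration from [hma_config()].
#' @param roi,refstack Optional precomputed stage outputs (reused if given).
#' @return List of `hma_raw` results, one per strategy, with the shared
#'   `hma_context` attached as attribute `context`.
#' @export
run_strategies <- function(image, strategies, config = hma_config(),
                           roi = NULL, refstack = NULL) {
  if (length(strategies) < 1) stop("need at least one strategy", call. = FALSE)
  image <- check_intensity_image(as_numeric_matrix(image))
  if (is.null(roi)) roi <- compute_roi(image, config)
  if (is.null(refstack)) refstack <- build_reference_stack(image, config$blur$layers)
  base_layer <- config$hierarchy$base_layer
  base_cm <- local_otsu_classify(refstack[[base_layer]]$image, roi,
                                 k = config$partition$k)
  ctx <- layer_context(base_cm, refstack, roi,
                       layer_bindings = config$hierarchy$layer_bindings,
                       k = config$partition$k)
  out <- vector("list", length(strategies))
  for (s in seq_along(strategies)) {
    expr <- parse_strategy(strategies[[s]])
    tops <- if (expr$kind == "union") expr$children else list(expr)
    layer_masks <- lapply(tops, function(node) {
      list(expr = format_strategy(structure(node, class = "hma_strategy")),
           mask = evaluate_strategy(structure(node, class = "hma_strategy"),
                                    ctx, config$partition$min_seed_distance),
           is_hole = is_hole_layer(node))
    })
    out[[s]] <- merge_to_raw(layer_masks, roi,
                             dilate_holes = config$hierarchy$dilate_holes,
                             min_fragment = config$hierarchy$min_fragment,
                             strategy_id = strategies[[s]])
  }
  attr(out, "context") <- ctx
  out
}

#' @exportS3Method base::print
print.hma_raw <- function(x, ...) {
  cat("raw segmentation result (", x$strategy_id, "): ",
      sum(x$mask), " pixels in ", max(label_mask(x$mask, 8L)), " patches\n",
      sep = "")
  invisible(x)
}
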