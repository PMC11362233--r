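#' @importFrom tibble tibble as_tibble
NULL

MISSING_BY_DESIGN <- -1L

#' Tree mappings: ordinal categories to pseudo-item responses
#'
#' A tree mapping is an integer table with one row per ordinal category
#' (`0..K_scale`) and one column per pseudo-item. Cells that are not reached
#' on a category's root-to-leaf path are missing by design and carry the
#' sentinel `-1` (printed as `"-"`); this sentinel is distinct from a
#' respondent's missing response (`NA` in the data).
#'
#' `mapping_agreement_intensity()` builds the agreement/intensity
#' decomposition of four- or six-point scales (agreement node, then an
#' intensity node on each side, categories ordered from least to most
#' intense). `mapping_midscale()` builds the five-point decomposition into
#' midscale, agreement, and extreme responding.
#'
#' @param table Integer matrix, rows = ordinal categories, columns =
#'   pseudo-items, `-1` for missing by design.
#' @param node_labels Optional pseudo-item labels.
#' @return An object of class `ditree_mapping`.
#' @export
tree_mapping <- function(table, node_labels = NULL) {
  table <- as.matrix(table)
  storage.mode(table) <- "integer"
  if (is.null(node_labels)) node_labels <- paste0("X", seq_len(ncol(table)))
  dimnames(table) <- list(as.character(seq_len(nrow(table)) - 1L), node_labels)
  K_h <- apply(table, 2L, function(x) max(x[x >= 0L]))
  obj <- structure(table, K_h = as.integer(K_h), class = "ditree_mapping")
  validate_mapping(obj)
  obj
}

validate_mapping <- function(mapping) {
  K_h <- attr(mapping, "K_h")
  for (h in seq_len(ncol(mapping))) {
    x <- mapping[, h]
    ok <- x == MISSING_BY_DESIGN | (x >= 0L & x <= K_h[h])
    if (!all(ok)) stop("mapping entries out of range", call. = FALSE)
  }
  # each ordinal category must map to a unique assignment
  keys <- apply(mapping, 1L, paste, collapse = ",")
  if (anyDuplicated(keys)) {
    stop("two ordinal categories map to the same pseudo-response pattern",
         call. = FALSE)
  }
  invisible(mapping)
}

#' @rdname tree_mapping
#' @param scale_points Number of response categories (4 or 6).
#' @export
mapping_agreement_intensity <- function(scale_points = 6) {
  if (scale_points == 6) {
    tab <- cbind(
      X1 = c(0L, 0L, 0L, 1L, 1L, 1L),
      X2 = c(-1L, -1L, -1L, 0L, 1L, 2L),
      X3 = c(2L, 1L, 0L, -1L, -1L, -1L)
    )
  } else if (scale_points == 4) {
    tab <- cbind(
      X1 = c(0L, 0L, 1L, 1L),
      X2 = c(-1L, -1L, 0L, 1L),
      X3 = c(1L, 0L, -1L, -1L)
    )
  } else {
    stop("scale_points must be 4 or 6", call. = FALSE)
  }
  tree_mapping(tab, c("agreement", "intensity|agree", "intensity|disagree"))
}

#' @rdname tree_mapping
#' @export
mapping_midscale <- function() {
  tab <- cbind(
    X1 = c(0L, 0L, 1L, 0L, 0L),
    X2 = c(0L, 0L, -1L, 1L, 1L),
    X3 = c(-1L, -1L, -1L, 0L, 1L),
    X4 = c(1L, 0L, -1L, -1L, -1L)
  )
  tree_mapping(tab, c("midscale", "agreement", "extreme|agree", "extreme|disagree"))
}

#' @export
print.ditree_mapping <- function(x, ...) {
  shown <- matrix(as.character(unclass(x)), nrow = nrow(x), dimnames = dimnames(x))
  shown[x == MISSING_BY_DESIGN] <- "-"
  cat("Tree mapping (rows = ordinal categories, '-' = missing by design):\n")
  print(shown, quote = FALSE)
  invisible(x)
}

#' Decompose an ordinal response into pseudo-item responses
#'
#' @param y Ordinal category (scalar, `0..K_scale`).
#' @param mapping A [tree_mapping()].
#' @return Named integer vector, one entry per pseudo-item, `-1` for missing
#'   by design.
#' @export
decompose_response <- function(y, mapping) {
  stopifnot(inherits(mapping, "ditree_mapping"), length(y) == 1L)
  if (is.na(y) || y < 0L || y > nrow(mapping) - 1L) {
    stop(sprintf("response %s out of range 0..%d", y, nrow(mapping) - 1L),
         call. = FALSE)
  }
  mapping[y + 1L, ]
}

# vectorized decomposition of an N x I ordinal response matrix into an
# N x (I*H) pseudo-response matrix; respondent-missing (NA) rows get NA
decompose_matrix <- function(Y, mapping) {
  Y <- as.matrix(Y)
  H <- ncol(mapping)
  N <- nrow(Y); I <- ncol(Y)
  out <- matrix(NA_integer_, N, I * H)
  for (i in seq_len(I)) {
    yi <- Y[, i]
    ok <- !is.na(yi)
    for (h in seq_len(H)) {
      out[ok, (i - 1L) * H + h] <- mapping[yi[ok] + 1L, h]
    }
  }
  out
}

# ---- model specifications -------------------------------------------------

new_tree_spec <- function(model, scale_points, mapping, nodes, traits, I) {
  params <- collect_params(nodes)
  structure(
    list(model = model, scale_points = scale_points, mapping = mapping,
         nodes = nodes, traits = traits, I = as.integer(I), params = params),
    class = "ditree_spec"
  )
}

collect_params <- function(nodes) {
  rows <- list()
  seen <- character()
  add <- function(name, type, node) {
    if (name %in% seen) return()
    seen <<- c(seen, name)
    rows[[length(rows) + 1L]] <<- tibble::tibble(name = name, type = type,
                                                 node = node)
  }
  for (h in seq_along(nodes)) {
    nd <- nodes[[h]]
    for (p in nd$processes) {
      add(p$disc, "disc", h)
      if (!is.null(p$loc) && p$loc$type == "param") add(p$loc$name, "loc", h)
    }
    for (tn in nd$tau) add(tn, "tau", h)
  }
  dplyr::bind_rows(rows)
}

#' @export
print.ditree_spec <- function(x, ...) {
  cat(sprintf("IRTree model spec '%s': %d-point scale, %d items, %d pseudo-items\n",
              x$model, x$scale_points, x$I, length(x$nodes)))
  for (h in seq_along(x$nodes)) {
    nd <- x$nodes[[h]]
    pr <- vapply(nd$processes, function(p) {
      sprintf("%s(%s, s=%s)", if (p$kind == "dominance") "D" else "I",
              p$trait, paste(p$weights, collapse = ","))
    }, "")
    cat(sprintf("  %s [K=%d]: %s\n", nd$label, nd$K, paste(pr, collapse = " + ")))
  }
  cat("  traits:", paste(sprintf("%s (%s)", names(x$traits), x$traits),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Build the agreement/intensity response-style tree for ideal-point items
#'
#' Three pseudo-items on a four- or six-point scale: an agreement node driven
#' by a trait-based ideal-point process, and two intensity nodes (given
#' agreement / disagreement). With `intensity = "both"` the intensity nodes
#' carry co-occurring processes -- an extreme-response-style (ERS) dominance
#' process with increasing weights and a trait ideal-point process whose
#' weights are reversed on the disagreement side; `"ers"` and `"trait"` give
#' the nested sequential-process models that keep only one of the two.
#' The ERS discrimination and the trait intensity discrimination are shared
#' across the two intensity nodes, and the item location is shared with the
#' agreement node.
#'
#' @param scale_points 4 or 6 (the agreement split requires an even scale).
#' @param item_count Number of items.
#' @param intensity Which processes act in the intensity nodes: `"both"`
#'   (co-occurring, model I-DI), `"ers"` (model I-D), or `"trait"` (model I-I).
#' @return A `ditree_spec`.
#' @export
irtree_ideal_ers <- function(scale_points = 6, item_count,
                             intensity = c("both", "ers", "trait")) {
  intensity <- match.arg(intensity)
  if (scale_points %% 2L != 0L) {
    stop("scale_points must be even (an agreement split must exist)",
         call. = FALSE)
  }
  if (!scale_points %in% c(4L, 6L)) stop("scale_points must be 4 or 6",
                                         call. = FALSE)
  Kh <- as.integer(scale_points / 2L - 1L)  # intensity nodes: K = 1 or 2
  mapping <- mapping_agreement_intensity(scale_points)
  loc <- list(type = "param", name = "delta")
  ers <- function() list(kind = "dominance", trait = "eta", weights = 0:Kh,
                         disc = "alpha")
  trait_up <- function() list(kind = "ideal_point", trait = "theta",
                              weights = 0:Kh, disc = "lambda2", loc = loc)
  trait_down <- function() list(kind = "ideal_point", trait = "theta",
                                weights = Kh:0, disc = "lambda2", loc = loc)
  pick <- function(up) switch(intensity,
    both = if (up) list(ers(), trait_up()) else list(ers(), trait_down()),
    ers = list(ers()),
    trait = if (up) list(trait_up()) else list(trait_down())
  )
  nodes <- list(
    list(K = 1L, label = "agreement",
         processes = list(list(kind = "ideal_point", trait = "theta",
                               weights = c(0, 1), disc = "lambda1", loc = loc)),
         tau = "tau1_1"),
    list(K = Kh, label = "intensity|agree", processes = pick(TRUE),
         tau = paste0("tau2_", seq_len(Kh))),
    list(K = Kh, label = "intensity|disagree", processes = pick(FALSE),
         tau = paste0("tau3_", seq_len(Kh)))
  )
  traits <- switch(intensity,
    both = c(theta = "substantive trait (ideal point)",
             eta = "extreme response style"),
    ers = c(theta = "substantive trait (ideal point)",
            eta = "extreme response style"),
    trait = c(theta = "substantive trait (ideal point)")
  )
  model <- switch(intensity, both = "I-DI", ers = "I-D", trait = "I-I")
  new_tree_spec(model, scale_points, mapping, nodes, traits, item_count)
}

#' Build the midscale/agreement/extreme tree for five-point dominance items
#'
#' Four pseudo-items: a midscale node with a co-occurring midscale
#' response-style (MRS) dominance process and a trait ideal-point process
#' whose location is tied to the agreement threshold (`delta_i = beta_2i =
#' tau_2i / alpha_2i`, by reference, so the tie survives estimation); a
#' trait-dominance agreement node; and two extreme nodes with co-occurring
#' ERS and trait dominance processes, the trait weights reversed on the
#' disagreement side. The ERS and trait extreme discriminations are shared
#' across the two extreme nodes.
#'
#' @param item_count Number of items.
#' @return A `ditree_spec`.
#' @export
irtree_midscale <- function(item_count) {
  tie <- list(type = "ratio", num = "tau2_1", den = "alpha2")
  nodes <- list(
    list(K = 1L, label = "midscale",
         processes = list(
           list(kind = "dominance", trait = "eta1", weights = c(0, 1),
                disc = "alpha1"),
           list(kind = "ideal_point", trait = "theta", weights = c(0, 1),
                disc = "lambda", loc = tie)),
         tau = "tau1_1"),
    list(K = 1L, label = "agreement",
         processes = list(list(kind = "dominance", trait = "theta",
                               weights = c(0, 1), disc = "alpha2")),
         tau = "tau2_1"),
    list(K = 1L, label = "extreme|agree",
         processes = list(
           list(kind = "dominance", trait = "eta2", weights = c(0, 1),
                disc = "alpha3"),
           list(kind = "dominance", trait = "theta", weights = c(0, 1),
                disc = "alpha4")),
         tau = "tau3_1"),
    list(K = 1L, label = "extreme|disagree",
         processes = list(
           list(kind = "dominance", trait = "eta2", weights = c(0, 1),
                disc = "alpha3"),
           list(kind = "dominance", trait = "theta", weights = c(1, 0),
                disc = "alpha4")),
         tau = "tau4_1")
  )
  traits <- c(theta = "substantive trait",
              eta1 = "midscale response style",
              eta2 = "extreme response style")
  new_tree_spec("midscale", 5L, mapping_midscale(), nodes, traits, item_count)
}

# resolve a node template plus one item's named parameters into a
# numeric pseudo_item
resolve_node <- function(node, item_params) {
  procs <- lapply(node$processes, function(p) {
    loc <- NULL
    if (!is.null(p$loc)) {
      loc <- if (p$loc$type == "param") unname(item_params[[p$loc$name]])
             else unname(item_params[[p$loc$num]] / item_params[[p$loc$den]])
    }
    process_spec(p$kind, p$trait, p$weights,
                 discrimination = unname(item_params[[p$disc]]), location = loc)
  })
  pseudo_item(procs, unlist(item_params[node$tau], use.names = FALSE),
              label = node$label)
}

#' Tree-implied category probabilities for one item
#'
#' Computes, for every person, the model-implied probability of each ordinal
#' category as the product of conditional pseudo-item probabilities along the
#' category's path (missing-by-design cells contribute nothing).
#'
#' @param spec A `ditree_spec`.
#' @param traits Data frame / matrix of person trait levels (columns named as
#'   in `spec$traits`), or a named vector for a single person.
#' @param item_params Named list or vector with the item's estimation-scale
#'   parameters (discriminations, location, category intercepts).
#' @return Matrix persons x ordinal categories; rows sum to 1.
#' @export
tree_category_probs <- function(spec, traits, item_params) {
  stopifnot(inherits(spec, "ditree_spec"))
  item_params <- as.list(item_params)
  tm <- resolve_traits(traits, names(spec$traits))
  mapping <- spec$mapping
  n <- nrow(tm)
  ncat <- nrow(mapping)
  lp <- matrix(0, n, ncat)
  for (h in seq_along(spec$nodes)) {
    item <- resolve_node(spec$nodes[[h]], item_params)
    lw <- dimirt_log_weights(tm, item)
    lnode <- lw - apply(lw, 1L, log_sum_exp)   # log node category probs
    for (y in seq_len(ncat)) {
      x <- mapping[y, h]
      if (x >= 0L) lp[, y] <- lp[, y] + lnode[, x + 1L]
    }
  }
  out <- exp(lp)
  dimnames(out) <- list(NULL, rownames(mapping))
  out
}

#' Probability of an ordinal response under an IRTree model
#'
#' @inheritParams tree_category_probs
#' @param y Ordinal category in `0..K_scale`.
#' @return Probability (vector over persons).
#' @export
tree_response_probability <- function(y, traits, spec, item_params) {
  probs <- tree_category_probs(spec, traits, item_params)
  if (any(y < 0L | y > ncol(probs) - 1L)) stop("y out of range", call. = FALSE)
  probs[, y + 1L]
}
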