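#' Define a single response process of a pseudo-item
#'
#' A process couples one latent trait to the pseudo-item's categories through
#' an item response function kind (dominance or ideal point), scoring weights,
#' a discrimination parameter, and -- for ideal-point processes -- an item
#' location.
#'
#' @param kind `"dominance"` (GPCM-type, monotone) or `"ideal_point"`
#'   (GGUM-type, unimodal and symmetric about `location`).
#' @param trait Name of the person variable driving the process (e.g.
#'   `"theta"`, `"eta"`).
#' @param weights Scoring weights `s_0, ..., s_K` relating the trait to the
#'   categories. Stored explicitly; reversed weights such as `c(2, 1, 0)` are
#'   first-class.
#' @param discrimination Positive discrimination (`alpha` for dominance,
#'   `lambda` for ideal point).
#' @param location Item location `delta`; required for ideal-point processes,
#'   must be absent for dominance processes.
#' @return An object of class `ditree_process`.
#' @examples
#' process_spec("dominance", "eta", weights = c(0, 1, 2), discrimination = 1.2)
#' @export
process_spec <- function(kind = c("dominance", "ideal_point"), trait, weights,
                         discrimination = 1, location = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(trait), length(trait) == 1L)
  if (!is.numeric(discrimination) || discrimination <= 0) {
    stop("discrimination must be > 0", call. = FALSE)
  }
  if (kind == "ideal_point" && is.null(location)) {
    stop("ideal-point processes require a location (delta)", call. = FALSE)
  }
  if (kind == "dominance" && !is.null(location)) {
    stop("dominance processes have no location parameter", call. = FALSE)
  }
  structure(
    list(kind = kind, trait = trait, weights = as.numeric(weights),
         discrimination = discrimination, location = location),
    class = "ditree_process"
  )
}

#' Define a pseudo-item with co-occurring response processes
#'
#' A pseudo-item has `K + 1` categories, `R >= 1` processes, and shared
#' category intercepts `tau_1, ..., tau_K` (`tau_0 = 0`). The intercepts are
#' the only identifiable combination of the process-specific thresholds; see
#' [category_intercepts()] for the generation-side arithmetic.
#'
#' @param processes List of [process_spec()] objects; all weight vectors must
#'   have the same length `K + 1`.
#' @param intercepts Category intercepts `tau_1, ..., tau_K`.
#' @param label Optional label used in error messages.
#' @return An object of class `ditree_pseudo_item`.
#' @export
pseudo_item <- function(processes, intercepts, label = "pseudo-item") {
  if (inherits(processes, "ditree_process")) processes <- list(processes)
  stopifnot(length(processes) >= 1L)
  K <- length(processes[[1L]]$weights) - 1L
  for (p in processes) {
    if (!inherits(p, "ditree_process")) {
      stop("processes must be process_spec() objects", call. = FALSE)
    }
    check_weights(p$weights, K, label)
  }
  if (length(intercepts) != K) {
    stop(sprintf("%s: expected %d category intercepts (tau_1..tau_K), got %d",
                 label, K, length(intercepts)), call. = FALSE)
  }
  structure(
    list(K = K, processes = processes, intercepts = as.numeric(intercepts),
         label = label),
    class = "ditree_pseudo_item"
  )
}

#' Category intercepts implied by process-specific thresholds
#'
#' When several processes co-occur, their threshold parameters cannot be
#' separated; only the weighted sum
#' `tau_k = sum_r alpha_r * beta_kr` (dominance) `+ lambda_r * xi_kr`
#' (ideal point) is identified, with `tau_0 = 0`. This is generation-side
#' arithmetic: estimation parameterizes `tau` directly.
#'
#' @param processes List of [process_spec()] objects.
#' @param thresholds List of numeric vectors (length `K` each), the
#'   process-specific thresholds aligned with `processes`.
#' @return Numeric vector `c(tau_0 = 0, tau_1, ..., tau_K)`.
#' @examples
#' pr <- list(
#'   process_spec("dominance", "theta", c(0, 1), discrimination = 1),
#'   process_spec("ideal_point", "theta", c(0, 1), discrimination = 1, location = 0)
#' )
#' category_intercepts(pr, list(0, -1))  # tau_1 = 1*0 + 1*(-1) = -1
#' @export
category_intercepts <- function(processes, thresholds) {
  if (inherits(processes, "ditree_process")) processes <- list(processes)
  stopifnot(length(processes) == length(thresholds))
  Ks <- lengths(thresholds)
  if (length(unique(Ks)) != 1L) {
    stop("all processes must supply the same number of thresholds", call. = FALSE)
  }
  K <- Ks[[1L]]
  tau <- numeric(K)
  for (r in seq_along(processes)) {
    tau <- tau + processes[[r]]$discrimination * as.numeric(thresholds[[r]])
  }
  c(tau0 = 0, stats::setNames(tau, paste0("tau", seq_len(K))))
}

# resolve traits argument into an N x T matrix with named columns
resolve_traits <- function(traits, needed) {
  if (is.data.frame(traits)) traits <- as.matrix(traits)
  if (is.null(dim(traits))) traits <- matrix(traits, nrow = 1,
                                             dimnames = list(NULL, names(traits)))
  missing <- setdiff(needed, colnames(traits))
  if (length(missing)) {
    stop(sprintf("missing trait level(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  traits
}

# N x (K+1) matrix of log category weights (unnormalized), Eq.-6 style:
# two linear predictors sharing the intercepts, differing in ideal-point
# scoring weights. Used by dimirt_probs and the tree machinery.
dimirt_log_weights <- function(traits_mat, item) {
  K <- item$K
  M <- 2 * K + 1
  cumtau <- c(0, cumsum(item$intercepts))
  n <- nrow(traits_mat)
  lp1 <- matrix(rep(-cumtau, each = n), nrow = n)
  lp2 <- lp1
  for (p in item$processes) {
    tv <- traits_mat[, p$trait]
    if (p$kind == "dominance") {
      term <- p$discrimination * outer(tv, p$weights)
      lp1 <- lp1 + term
      lp2 <- lp2 + term
    } else {
      d <- tv - p$location
      lp1 <- lp1 + p$discrimination * outer(d, p$weights)
      lp2 <- lp2 + p$discrimination * outer(d, M - p$weights)
    }
  }
  log_add_exp(lp1, lp2)
}

#' DI-MIRT category probabilities (linear-predictor form)
#'
#' Combines the `R` co-occurring processes of a pseudo-item into one category
#' distribution by summing the process-specific linear predictors inside each
#' of the two exponential terms of the divide-by-total form. With a single
#' dominance process this reproduces [gpcm_probs()] exactly; with a single
#' ideal-point process it reproduces [ggum_probs()].
#'
#' @param traits Named numeric vector of trait levels (one person), or a data
#'   frame / matrix with one named column per trait (one row per person).
#' @param item A [pseudo_item()].
#' @return Probability vector (single person) or matrix (persons x categories).
#' @export
dimirt_probs <- function(traits, item) {
  stopifnot(inherits(item, "ditree_pseudo_item"))
  tm <- resolve_traits(traits, vapply(item$processes, `[[`, "", "trait"))
  out <- softmax_rows(dimirt_log_weights(tm, item))
  if (nrow(out) == 1L) drop(out) else out
}

#' Aggregate process-specific distributions into a joint distribution
#'
#' The probability-based formulation of co-occurrence: the joint category
#' distribution is the softmax of the summed log probabilities of the
#' process-specific distributions. For pseudo-items with at most one
#' ideal-point process this is equivalent to the linear-predictor form of
#' [dimirt_probs()]; with two or more ideal-point processes the product of
#' two-term components introduces cross terms and the two formulations can
#' differ numerically (see the methods vignette).
#'
#' @param process_probs List of strictly positive probability vectors of equal
#'   length.
#' @return A probability vector of the same length.
#' @export
aggregate_probability_form <- function(process_probs) {
  stopifnot(is.list(process_probs), length(process_probs) >= 1L)
  len <- lengths(process_probs)
  if (length(unique(len)) != 1L) {
    stop("all process distributions must have the same length", call. = FALSE)
  }
  for (p in process_probs) {
    if (any(p <= 0)) {
      stop("process distributions must be strictly positive (log undefined at 0)",
           call. = FALSE)
    }
  }
  lw <- Reduce(`+`, lapply(process_probs, log))
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Per-process category distributions of a pseudo-item
#'
#' Evaluates each process of a pseudo-item in isolation (GPCM for dominance,
#' GGUM for ideal point), with the pseudo-item's category intercepts divided
#' by the process discrimination so that the process-specific thresholds used
#' here reproduce the shared intercepts under [category_intercepts()] when a
#' single process carries all of `tau`. Mainly useful together with
#' [aggregate_probability_form()] as an independent computation route.
#'
#' @inheritParams dimirt_probs
#' @param thresholds Optional list of process-specific thresholds (length `K`
#'   each). When omitted, the item's intercepts are attributed to the first
#'   process and the remaining processes get zero thresholds.
#' @return List of probability vectors, one per process (single person only).
#' @export
process_distributions <- function(traits, item, thresholds = NULL) {
  stopifnot(inherits(item, "ditree_pseudo_item"))
  tm <- resolve_traits(traits, vapply(item$processes, `[[`, "", "trait"))
  stopifnot(nrow(tm) == 1L)
  R <- length(item$processes)
  if (is.null(thresholds)) {
    thresholds <- c(list(item$intercepts / item$processes[[1L]]$discrimination),
                    rep(list(numeric(item$K)), R - 1L))
  }
  stopifnot(length(thresholds) == R)
  out <- vector("list", R)
  for (r in seq_len(R)) {
    p <- item$processes[[r]]
    tv <- tm[1L, p$trait]
    out[[r]] <- if (p$kind == "dominance") {
      gpcm_probs(tv, p$discrimination, thresholds[[r]], p$weights)
    } else {
      ggum_probs(tv, p$discrimination, p$location, thresholds[[r]], p$weights)
    }
  }
  out
}
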