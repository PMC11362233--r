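#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries of a fitted IRTree model
#'
#' @param x A `ditree_fit`.
#' @param pars Optional regular expression selecting parameters (e.g.
#'   `"^delta"`, `"^theta\\\\["`).
#' @param level Credible-interval level.
#' @param ... Unused.
#' @return Tibble with one row per parameter: posterior mean, sd, credible
#'   bounds, and (when available) R-hat and bulk/tail ESS.
#' @export
tidy.ditree_fit <- function(x, pars = NULL, level = 0.95, ...) {
  pooled <- do.call(rbind, x$chains)
  keep <- colnames(pooled)
  if (!is.null(pars)) keep <- grep(pars, keep, value = TRUE)
  a <- (1 - level) / 2
  out <- tibble::tibble(
    parameter = keep,
    estimate = colMeans(pooled[, keep, drop = FALSE]),
    std.error = apply(pooled[, keep, drop = FALSE], 2L, sd),
    conf.low = apply(pooled[, keep, drop = FALSE], 2L, quantile, a,
                     names = FALSE),
    conf.high = apply(pooled[, keep, drop = FALSE], 2L, quantile, 1 - a,
                      names = FALSE)
  )
  if (!is.null(x$diagnostics)) {
    out <- dplyr::left_join(out, x$diagnostics, by = "parameter")
  }
  out
}

#' One-row summary of a fitted IRTree model
#'
#' @param x A `ditree_fit`.
#' @param ... Unused.
#' @return One-row tibble: model, data size, sampler bookkeeping, worst
#'   diagnostics, convergence and orientation flags.
#' @export
glance.ditree_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model,
    N = x$N, I = x$spec$I,
    chains = length(x$chains),
    draws_per_chain = x$total_draws,
    extensions = x$extensions,
    max_rhat = if (is.null(x$diagnostics)) NA_real_
               else max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_bulk = if (is.null(x$diagnostics)) NA_real_
                   else min(x$diagnostics$ess_bulk, na.rm = TRUE),
    min_ess_tail = if (is.null(x$diagnostics)) NA_real_
                   else min(x$diagnostics$ess_tail, na.rm = TRUE),
    converged = x$converged,
    orientation_ok = x$orientation_ok
  )
}

#' Diagnostic overview plot for a fitted model
#'
#' Histogram of split R-hat values over all parameters with the convergence
#' threshold marked.
#'
#' @param object A `ditree_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ditree_fit <- function(object, ...) {
  stopifnot(!is.null(object$diagnostics))
  ggplot2::ggplot(object$diagnostics, ggplot2::aes(x = .data$rhat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$control$rhat_max,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "split R-hat (rank-normalized)", y = "parameters",
                  title = sprintf("Convergence diagnostics: %s model",
                                  object$spec$model)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Item response function / category probability curves
#'
#' Plots the category probability curves (and optionally the expected-score
#' IRF) of one pseudo-item over a trait grid, in the style of standard
#' GPCM/GGUM illustrations. For multi-trait pseudo-items the remaining traits
#' are held at `fixed`.
#'
#' @param item A [pseudo_item()].
#' @param trait Name of the trait varied on the x axis.
#' @param fixed Named numeric vector of the other traits' levels.
#' @param grid Trait grid.
#' @return A ggplot object.
#' @export
plot_category_curves <- function(item, trait = "theta", fixed = NULL,
                                 grid = seq(-4, 4, length.out = 201)) {
  stopifnot(inherits(item, "ditree_pseudo_item"))
  traits <- unique(vapply(item$processes, `[[`, "", "trait"))
  others <- setdiff(traits, trait)
  base <- stats::setNames(rep(0, length(others)), others)
  if (!is.null(fixed)) base[names(fixed)] <- fixed
  tm <- cbind(stats::setNames(data.frame(grid), trait),
              as.data.frame(as.list(base)))
  probs <- dimirt_probs(tm, item)
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(!!trait := grid),
                     tibble::as_tibble(as.data.frame(probs),
                                       .name_repair = ~ paste0("y=", seq_along(.x) - 1))),
    -dplyr::all_of(trait), names_to = "category", values_to = "p")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[trait]], y = .data$p,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "category probability", title = item$label) +
    ggplot2::theme_minimal()
}

#' Category-frequency plot of a simulated dataset
#'
#' @param object A `ditree_sim`.
#' @param ... Unused.
#' @return A ggplot object showing observed category proportions per item.
#' @export
autoplot.ditree_sim <- function(object, ...) {
  Y <- object$responses
  df <- tibble::tibble(
    item = rep(seq_len(ncol(Y)), each = nrow(Y)),
    category = factor(as.vector(Y))
  )
  ggplot2::ggplot(stats::na.omit(df),
                  ggplot2::aes(x = factor(.data$item), fill = .data$category)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = "item", y = "proportion",
                  title = sprintf("Simulated %s responses", object$design$model)) +
    ggplot2::theme_minimal()
}
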