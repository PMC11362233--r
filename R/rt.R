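#' Manifest response-time predictors from five-point responses
#'
#' Builds the indicator matrices used by the log-RT mixed model: `middle` is 1
#' where the middle category (2) was selected, `extreme` is 1 where either
#' outermost category (0 or 4) was selected; the two extreme pseudo-items
#' share one coefficient. Missing responses yield 0 indicators and are masked
#' out of the RT likelihood (dropped pairwise).
#'
#' @param responses Integer matrix persons x items with categories `0..4`.
#' @return List with numeric matrices `middle` and `extreme`.
#' @export
build_rt_design <- function(responses) {
  responses <- as.matrix(responses)
  rng <- range(responses, na.rm = TRUE)
  if (rng[1] < 0L || rng[2] > 4L) {
    stop("response-time design requires a five-point scale (categories 0..4)",
         call. = FALSE)
  }
  middle <- 1 * (responses == 2L)
  extreme <- 1 * (responses == 0L | responses == 4L)
  middle[is.na(middle)] <- 0
  extreme[is.na(extreme)] <- 0
  list(middle = middle, extreme = extreme)
}

#' Fixed effects of a joint response-time fit
#'
#' Posterior means and credible intervals of the RT fixed effects and
#' variance components of a [fit_joint_rt_model()] fit.
#'
#' @param fit A `ditree_fit` fitted with response times.
#' @param level Credible-interval level (default 0.95).
#' @return Tibble with columns `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
rt_fixed_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ditree_fit"))
  pooled <- do.call(rbind, fit$chains)
  terms <- c(rt_gamma_names, "rt_sd_person", "rt_sd_item", "rt_sd_resid")
  terms <- terms[terms %in% colnames(pooled)]
  if (!length(terms)) {
    stop("fit contains no response-time block; use fit_joint_rt_model()",
         call. = FALSE)
  }
  a <- (1 - level) / 2
  purrr::map_dfr(terms, function(tm) {
    x <- pooled[, tm]
    tibble::tibble(term = tm, estimate = mean(x),
                   conf.low = quantile(x, a, names = FALSE),
                   conf.high = quantile(x, 1 - a, names = FALSE))
  })
}
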