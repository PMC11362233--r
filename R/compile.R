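# Internal: translate a ditree_spec into the flat numeric description used by
# the compiled likelihood engine.
#
# Parameter columns of the expanded item-parameter matrix follow
# spec$params$name order; trait columns follow names(spec$traits).
compile_spec <- function(spec) {
  pnames <- spec$params$name
  tnames <- names(spec$traits)
  col_of <- function(name) {
    j <- match(name, pnames)
    if (is.na(j)) stop(sprintf("unresolved parameter reference '%s'", name),
                       call. = FALSE)
    j - 1L
  }
  nodes <- lapply(spec$nodes, function(nd) {
    R <- length(nd$processes)
    kind <- integer(R); trait <- integer(R); disc <- integer(R)
    loc_type <- integer(R); loc1 <- integer(R); loc2 <- integer(R)
    w <- matrix(0, R, nd$K + 1L)
    for (r in seq_len(R)) {
      p <- nd$processes[[r]]
      kind[r] <- if (p$kind == "dominance") 1L else 0L
      ti <- match(p$trait, tnames)
      if (is.na(ti)) stop(sprintf("trait '%s' not registered in spec", p$trait),
                          call. = FALSE)
      trait[r] <- ti - 1L
      disc[r] <- col_of(p$disc)
      if (is.null(p$loc)) {
        loc_type[r] <- 0L
      } else if (p$loc$type == "param") {
        loc_type[r] <- 1L; loc1[r] <- col_of(p$loc$name)
      } else {
        loc_type[r] <- 2L; loc1[r] <- col_of(p$loc$num); loc2[r] <- col_of(p$loc$den)
      }
      w[r, ] <- p$weights
    }
    list(K = nd$K, tau_cols = vapply(nd$tau, col_of, 0L),
         kind = kind, trait = trait, disc = disc,
         loc_type = loc_type, loc1 = loc1, loc2 = loc2, weights = w)
  })
  list(nodes = nodes, param_names = pnames, trait_names = tnames,
       H = length(spec$nodes))
}

# Internal: items tibble (one row per item, estimation-scale columns) -> the
# I x P matrix expected by the engine.
items_to_ipar <- function(spec, items) {
  pnames <- spec$params$name
  missing <- setdiff(pnames, names(items))
  if (length(missing)) {
    stop(sprintf("items table lacks parameter column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.matrix(as.data.frame(items)[, pnames, drop = FALSE])
}

# Internal: convenience wrapper around the compiled engine.
# reduce: "matrix" (N x I), "person", "item", "sum"
tree_loglik <- function(theta, ipar, X, compiled,
                        which_nodes = seq_len(compiled$H),
                        reduce = "sum") {
  code <- switch(reduce, matrix = 0L, person = 1L, item = 2L, sum = 3L)
  ll_tree_engine(theta, ipar, X, compiled$nodes, as.integer(which_nodes), code)
}
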