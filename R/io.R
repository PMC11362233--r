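# Plain-text interchange: parameter tables, tree mappings, model specs.

#' Read and write item-parameter tables
#'
#' Long CSV layout with columns `item_id`, `param_name`, `category_index`,
#' `value`. Values are written with 17 significant digits so a round trip
#' reproduces the doubles bit for bit. `category_index` is parsed from a
#' trailing `_<k>` in the column name (e.g. `tau2_1`) and is `NA` for scalar
#' parameters.
#'
#' @param items Tibble with an `item` column and one numeric column per
#'   parameter.
#' @param path File path.
#' @return `write_param_table()` returns `path` invisibly;
#'   `read_param_table()` returns the wide tibble.
#' @export
write_param_table <- function(items, path) {
  stopifnot("item" %in% names(items))
  long <- tidyr::pivot_longer(items, -dplyr::all_of("item"),
                              names_to = "param_name", values_to = "value")
  m <- regmatches(long$param_name, regexec("^(.*)_([0-9]+)$", long$param_name))
  long$category_index <- vapply(m, function(x)
    if (length(x)) as.integer(x[3]) else NA_integer_, 0L)
  out <- data.frame(item_id = long$item, param_name = long$param_name,
                    category_index = long$category_index,
                    value = format(long$value, digits = 17, scientific = TRUE,
                                   trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_param_table
#' @export
read_param_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"))
  raw$value <- as.numeric(raw$value)
  wide <- tidyr::pivot_wider(tibble::as_tibble(raw[c("item_id", "param_name", "value")]),
                             names_from = "param_name", values_from = "value")
  dplyr::rename(wide, item = "item_id")
}

#' Read and write tree mappings as CSV
#'
#' Rows are ordinal categories, columns pseudo-items, `-` marks cells that are
#' missing by design.
#'
#' @param mapping A [tree_mapping()].
#' @param path File path.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "ditree_mapping"))
  shown <- matrix(as.character(unclass(mapping)), nrow = nrow(mapping),
                  dimnames = dimnames(mapping))
  shown[mapping == MISSING_BY_DESIGN] <- "-"
  utils::write.csv(cbind(category = rownames(mapping), shown), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tab <- as.matrix(raw[, -1, drop = FALSE])
  tab[tab == "-"] <- "-1"
  storage.mode(tab) <- "integer"
  tree_mapping(tab, colnames(raw)[-1])
}

#' Serialize a model spec to JSON
#'
#' Writes the pseudo-item structure (categories, processes with IRF kind,
#' trait, weights, discrimination and location identifiers, intercept
#' identifiers), trait register, mapping table and scale metadata.
#'
#' @param spec A `ditree_spec`.
#' @param path File path.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "ditree_spec"))
  nodes <- lapply(spec$nodes, function(nd) {
    list(K = nd$K, label = nd$label,
         processes = lapply(nd$processes, function(p) {
           out <- list(irf = p$kind, trait = p$trait, weights = p$weights,
                       discrimination_id = p$disc)
           if (!is.null(p$loc)) {
             out$location_id <- if (p$loc$type == "param") p$loc$name
                                else list(ratio = c(p$loc$num, p$loc$den))
           }
           out
         }),
         intercept_ids = as.list(nd$tau))
  })
  obj <- list(model = spec$model, scale_points = spec$scale_points,
              item_count = spec$I,
              traits = as.list(spec$traits),
              mapping = unclass(spec$mapping),
              node_labels = colnames(spec$mapping),
              nodes = nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  nodes <- lapply(obj$nodes, function(nd) {
    list(K = as.integer(nd$K), label = nd$label,
         processes = lapply(nd$processes, function(p) {
           loc <- NULL
           if (!is.null(p$location_id)) {
             loc <- if (is.list(p$location_id)) {
               list(type = "ratio", num = p$location_id$ratio[[1]],
                    den = p$location_id$ratio[[2]])
             } else list(type = "param", name = p$location_id)
           }
           list(kind = p$irf, trait = p$trait, weights = as.numeric(p$weights),
                disc = p$discrimination_id, loc = loc)
         }),
         tau = unlist(nd$intercept_ids))
  })
  mapping <- tree_mapping(matrix(as.integer(obj$mapping),
                                 nrow = obj$scale_points),
                          obj$node_labels)
  new_tree_spec(obj$model, as.integer(obj$scale_points), mapping, nodes,
                unlist(obj$traits), as.integer(obj$item_count))
}

#' Read and write wide response matrices as CSV
#'
#' @param responses Integer matrix persons x items.
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  df <- as.data.frame(responses)
  names(df) <- paste0("item", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  as.matrix(utils::read.csv(path))
}
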