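# Tabular I/O dialect: TSV with a header row; the first column ("sample_id")
# carries sample ids for sample-by-feature tables.

#' Read a samples-by-features TSV (first column = sample ids)
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_view_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a named vector TSV (sample_id, value)
#' @param path file path.
#' @return named vector (numeric, or integer for label files).
#' @export
read_vector_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stats::setNames(df[[2]], as.character(df[[1]]))
}

write_view_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_vector_tsv <- function(v, path, value_name = "value") {
  df <- data.frame(sample_id = names(v), v, check.names = FALSE)
  names(df)[2] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated dataset to a directory
#'
#' Emits \code{X.tsv}, \code{Y.tsv}, \code{Z.tsv}, \code{labels.tsv} and the
#' generating configuration as \code{config.json}.
#'
#' @param data a \code{"multiview_data"}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_multiview <- function(data, dir) {
  stopifnot(inherits(data, "multiview_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("X.tsv", "Y.tsv", "Z.tsv", "labels.tsv",
                            "config.json"))
  write_view_tsv(data$X, paths[1])
  write_view_tsv(data$Y, paths[2])
  write_vector_tsv(data$Z, paths[3], "z")
  write_vector_tsv(data$labels, paths[4], "cluster")
  jsonlite::write_json(unclass(data$config), paths[5], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

# Persist every pipeline intermediate plus a manifest of content hashes.
write_pipeline_artifacts <- function(res, out_dir, top_fraction = 0.01) {
  p_sim <- file.path(out_dir, "similarity.tsv")
  utils::write.table(res$similarity$S, p_sim, sep = "\t", quote = FALSE)

  mods <- lapply(seq_along(res$modules), function(i) {
    m <- res$modules[[i]]
    list(module_id = i,
         x_features = res$similarity$feature_ids[m$x_members],
         y_features = res$similarity$feature_ids[m$y_members])
  })
  p_mod <- file.path(out_dir, "modules.json")
  jsonlite::write_json(mods, p_mod, auto_unbox = TRUE)

  g <- res$isns$global
  ei <- res$isns$edge_index
  p_glob <- file.path(out_dir, "global_network.tsv")
  utils::write.table(
    data.frame(node_i = g$node_ids[ei[, 1]], node_j = g$node_ids[ei[, 2]],
               weight = g$edge_weights[ei]),
    p_glob, sep = "\t", quote = FALSE, row.names = FALSE)

  p_isn <- file.path(out_dir, "isn.tsv")
  write_view_tsv(res$isns$W, p_isn)

  hm <- res$clustering$linkage
  p_link <- file.path(out_dir, "linkage.tsv")
  utils::write.table(
    data.frame(left = hm$merge[, 1], right = hm$merge[, 2],
               height = hm$height,
               size = merge_sizes(hm$merge)),
    p_link, sep = "\t", quote = FALSE, row.names = FALSE)

  p_lab <- file.path(out_dir, "labels.tsv")
  write_vector_tsv(res$clustering$labels, p_lab, "cluster")

  p_rep <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(res$report), p_rep, auto_unbox = TRUE,
                       digits = NA)

  curves <- curves_by_cluster(res$isns, res$clustering$labels)
  p_cur <- file.path(out_dir, "filtration_curves.tsv")
  utils::write.table(curves, p_cur, sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- c(p_sim, p_mod, p_glob, p_isn, p_link, p_lab, p_rep, p_cur)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(paths)
}

#' Write a binary network as an edge-list TSV
#'
#' @param network a \code{"binary_network"} from [binarize_top_edges()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_binary_network <- function(network, path) {
  stopifnot(inherits(network, "binary_network"))
  ei <- edge_index(nrow(network$adjacency))
  on <- network$adjacency[ei] != 0
  utils::write.table(
    data.frame(node_i = network$node_ids[ei[on, 1]],
               node_j = network$node_ids[ei[on, 2]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the node list of a largest connected component as plain text
#'
#' @param lcc output of [largest_connected_component()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_lcc_nodes <- function(lcc, path) {
  ids <- if (is.null(lcc$node_ids)) as.character(lcc$nodes) else lcc$node_ids
  writeLines(ids, path)
  invisible(path)
}

merge_sizes <- function(merge) {
  sizes <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    sz <- function(x) if (x < 0) 1L else sizes[x]
    sizes[i] <- sz(merge[i, 1]) + sz(merge[i, 2])
  }
  sizes
}
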