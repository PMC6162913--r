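# Cross-dataset co-occurrence network of pathofunctions (or genus-level
# carriers): an edge connects two entities when their abundances
# correlate (Spearman rho > 0.35, p and q < 0.05, BH within dataset) in
# at least three datasets; edge width is the number of supporting
# datasets, node size the median abundance over all samples.

#' Co-occurrence network configuration
#'
#' @param rho_threshold Spearman rho support threshold (strict `>`).
#' @param p_threshold,q_threshold p / BH-q support thresholds (strict
#'   `<`); the q family is all entity pairs within one dataset.
#' @param min_datasets Minimum number of supporting datasets per edge.
#' @param merge_map Optional named character vector merging datasets
#'   before correlation (e.g. `c(IV = "IV+VI", VI = "IV+VI")` for
#'   cohorts with overlapping control samples).
#' @return List of class `network_config`.
#' @export
network_config <- function(rho_threshold = 0.35, p_threshold = 0.05,
                           q_threshold = 0.05, min_datasets = 3L,
                           merge_map = NULL) {
  stopifnot(rho_threshold > 0, rho_threshold < 1,
            p_threshold > 0, p_threshold < 1,
            q_threshold > 0, q_threshold < 1, min_datasets >= 1L)
  structure(list(rho_threshold = rho_threshold, p_threshold = p_threshold,
                 q_threshold = q_threshold,
                 min_datasets = as.integer(min_datasets),
                 merge_map = merge_map),
            class = "network_config")
}

#' Build the cross-dataset co-occurrence network
#'
#' For every pair of entities (pathways or genus-level carriers) and
#' every dataset, the Spearman correlation of their abundances over the
#' dataset's samples is computed; q-values are BH-adjusted over all
#' pairs within the dataset.  A dataset supports a pair when
#' `p < p_threshold`, `q < q_threshold` and `rho > rho_threshold`
#' (strictly; negative correlations never create edges, though the mean
#' rho is retained as edge metadata).  Pairs supported by at least
#' `min_datasets` datasets become edges with width = support count.
#' Node size is the median abundance over all samples of all datasets,
#' zero values included.  A dataset lacking an entity (column absent or
#' all NA) abstains for that entity's pairs.
#'
#' @param tables Named list of per-dataset abundance tables (each a
#'   data.frame with `sample_id` plus one numeric column per entity).
#' @param config A [network_config()].
#' @return List of class `co_network`: `nodes` (entity,
#'   median_abundance), `edges` (entity_a, entity_b, width, mean_rho),
#'   `support` (per dataset x pair detail) and `graph` (igraph object).
#' @export
build_network <- function(tables, config = network_config()) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stopf("tables must be a named list (dataset ids)")
  if (!is.null(config$merge_map)) {
    grp <- names(tables)
    hit <- grp %in% names(config$merge_map)
    grp[hit] <- config$merge_map[grp[hit]]
    tables <- lapply(split(tables, grp), function(ts)
      do.call(rbind, lapply(ts, function(t) t[, names(ts[[1L]])])))
  }
  if (length(tables) < config$min_datasets)
    stopf("fewer datasets (%d) than min_datasets (%d)",
          length(tables), config$min_datasets)

  entities <- sort(unique(unlist(lapply(tables, function(t)
    setdiff(names(t), "sample_id")))))
  if (length(entities) < 2L) stopf("need at least two entities")
  pairs <- t(combn(entities, 2L))

  support <- list()
  for (d in names(tables)) {
    tab <- tables[[d]]
    avail <- entities[entities %in% names(tab)]
    avail <- avail[vapply(avail, function(e) any(!is.na(tab[[e]])),
                          logical(1))]
    rows <- lapply(seq_len(nrow(pairs)), function(k) {
      a <- pairs[k, 1L]; b <- pairs[k, 2L]
      if (!a %in% avail || !b %in% avail) return(NULL)
      st <- tryCatch(spearman_test(tab[[a]], tab[[b]]),
                     error = function(e) NULL)
      if (is.null(st)) return(NULL)
      data.frame(dataset = d, entity_a = a, entity_b = b,
                 rho = st$rho, p = st$p, n = st$n, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows) || nrow(rows) == 0L) next
    rows$q <- bh_adjust(rows$p)
    rows$supports <- !is.na(rows$rho) & rows$rho > config$rho_threshold &
      !is.na(rows$p) & rows$p < config$p_threshold &
      rows$q < config$q_threshold
    support[[d]] <- rows
  }
  support <- if (length(support)) do.call(rbind, c(support, make.row.names = FALSE))
             else data.frame(dataset = character(), entity_a = character(),
                             entity_b = character(), rho = numeric(),
                             p = numeric(), n = integer(), q = numeric(),
                             supports = logical(), stringsAsFactors = FALSE)

  key <- paste(support$entity_a, support$entity_b, sep = "\r")
  edge_rows <- lapply(split(support, key), function(s) {
    w <- sum(s$supports)
    data.frame(entity_a = s$entity_a[1L], entity_b = s$entity_b[1L],
               width = w, mean_rho = mean(s$rho[s$supports]),
               stringsAsFactors = FALSE)
  })
  edges <- if (length(edge_rows))
    do.call(rbind, c(edge_rows, make.row.names = FALSE))
  else data.frame(entity_a = character(), entity_b = character(),
                  width = integer(), mean_rho = numeric(),
                  stringsAsFactors = FALSE)
  edges <- edges[edges$width >= config$min_datasets, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(entity = entities, stringsAsFactors = FALSE)
  nodes$median_abundance <- vapply(entities, function(e) {
    v <- unlist(lapply(tables, function(t)
      if (e %in% names(t)) t[[e]] else NULL))
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else median(v)
  }, numeric(1))

  g <- igraph::graph_from_data_frame(
    edges[, c("entity_a", "entity_b", "width", "mean_rho")],
    directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, support = support,
                 graph = g, config = config),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (support >= %d datasets)\n",
              nrow(x$nodes), nrow(x$edges), x$config$min_datasets))
  invisible(x)
}

#' Export a co-occurrence network
#'
#' Writes the edge list as TSV and the graph as GraphML (node attribute
#' `median_abundance`, edge attributes `width` and `mean_rho`).
#'
#' @param net A `co_network`.
#' @param edge_tsv,graphml Output paths (NULL to skip either).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, edge_tsv = NULL, graphml = NULL) {
  stopifnot(inherits(net, "co_network"))
  if (!is.null(edge_tsv)) write_tsv(net$edges, edge_tsv)
  if (!is.null(graphml))
    igraph::write_graph(net$graph, graphml, format = "graphml")
  invisible(c(edge_tsv, graphml))
}
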