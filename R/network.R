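# Two-domain correlation networks: pairwise-complete Pearson correlation
# over the 12 measures, significance-gated ("full") and |r|-thresholded
# network construction, degree centrality, and lossless export.

#' Build a subjects-by-measures table
#'
#' @param data Data frame holding (at least) the measure columns; extra
#'   columns such as `subject_id` and `group` are carried along.
#' @param measures Measure column names (default: the canonical 12 that are
#'   present in `data`).
#' @return A `measure_table` data frame; the measure names and domains are
#'   stored in attribute `"measures"`.
#' @export
measure_table <- function(data, measures = intersect(measure_info()$measure,
                                                     names(data))) {
  if (length(measures) < 2) stop("need at least 2 measure columns")
  missing_cols <- setdiff(measures, names(data))
  if (length(missing_cols)) {
    stop("measure columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  info <- measure_info()
  attr(data, "measures") <- info[info$measure %in% measures, , drop = FALSE]
  class(data) <- c("measure_table", "data.frame")
  data
}

#' Pairwise-complete correlation table over a measure table
#'
#' Pearson r, p and n for every unordered measure pair, using only subjects
#' with both values present. Pairs with fewer than 3 complete observations
#' (or a constant measure) get `NA` with a warning.
#'
#' @param measures A [measure_table()].
#' @return A `corr_table` data frame (see [load_correlation_tables()]), with
#'   p-values and significance codes derived from them.
#' @export
correlation_table <- function(measures) {
  stopifnot(inherits(measures, "measure_table"))
  info <- attr(measures, "measures")
  nm <- info$measure
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    x <- measures[[m1]]; y <- measures[[m2]]
    ok <- !is.na(x) & !is.na(y)
    res <- if (sum(ok) >= 3 && stats::var(x[ok]) > 0 && stats::var(y[ok]) > 0) {
      tryCatch(pearson(x[ok], y[ok]), error = function(e) NULL)
    } else NULL
    if (is.null(res)) {
      warning("insufficient complete pairs for ", m1, "-", m2,
              "; marked missing", call. = FALSE)
      data.frame(measure1 = m1, measure2 = m2, r = NA_real_, p = NA_real_,
                 n = sum(ok), stringsAsFactors = FALSE)
    } else {
      data.frame(measure1 = m1, measure2 = m2, r = res$estimate,
                 p = res$p_value, n = res$n, stringsAsFactors = FALSE)
    }
  })
  .new_corr_table(do.call(rbind, rows))
}

.new_network <- function(nodes, edges, mode, param) {
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = mode, param = param),
            class = "measure_network")
}

.nodes_from_corr <- function(corr) {
  nm <- unique(c(corr$measure1, corr$measure2))
  canon <- measure_info()
  nm <- c(intersect(canon$measure, nm), setdiff(nm, canon$measure))
  data.frame(name = nm, domain = .measure_domain(nm), stringsAsFactors = FALSE)
}

.edges_df <- function(corr, keep) {
  data.frame(from = corr$measure1[keep], to = corr$measure2[keep],
             weight = corr$r[keep], sign = sign(corr$r[keep]),
             sig_code = corr$sig_code[keep], stringsAsFactors = FALSE)
}

#' Build the full (significance-gated) network
#'
#' An edge joins every measure pair whose correlation is significant at
#' `alpha`: by exact p-value when available, otherwise by the printed
#' significance code (codes whose level is at or below `alpha`; the p < 0.1
#' marks are excluded at the default `alpha = 0.05`). Edge weights carry the
#' sign of the correlation.
#'
#' @param corr A `corr_table`.
#' @param alpha Significance level (default 0.05).
#' @return A `measure_network` with `mode = "full"`.
#' @export
build_full_network <- function(corr, alpha = 0.05) {
  stopifnot(inherits(corr, "corr_table"), alpha > 0, alpha <= 1)
  has_p <- !is.na(corr$p)
  has_code <- !is.na(corr$sig_code)
  usable <- has_p | has_code
  if (any(!usable)) {
    warning(sum(!usable), " pair(s) without p-value or code skipped",
            call. = FALSE)
  }
  keep <- usable &
    ifelse(has_p, corr$p < alpha,
           .sig_code_bound(corr$sig_code) <= alpha + 1e-12) &
    !is.na(corr$r)
  .new_network(.nodes_from_corr(corr), .edges_df(corr, keep), "full", alpha)
}

#' Build the thresholded network
#'
#' An edge joins every measure pair with `|r| > tau` (strict).
#'
#' @param corr A `corr_table`.
#' @param tau Absolute-correlation threshold (default 0.4).
#' @return A `measure_network` with `mode = "thresholded"`.
#' @export
build_thresholded_network <- function(corr, tau = 0.4) {
  stopifnot(inherits(corr, "corr_table"), tau >= 0)
  keep <- !is.na(corr$r) & abs(corr$r) > tau
  .new_network(.nodes_from_corr(corr), .edges_df(corr, keep),
               "thresholded", tau)
}

#' Degree centrality of network nodes
#'
#' Number of incident edges per node; [cross_domain_degree()] counts only
#' neighbours in the opposite domain (cognitive vs oculomotor).
#'
#' @param network A `measure_network`.
#' @param node Optional node name(s); default all nodes.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(network, node = NULL) {
  stopifnot(inherits(network, "measure_network"))
  nodes <- network$nodes$name
  if (is.null(node)) node <- nodes
  if (!all(node %in% nodes)) {
    stop("unknown node(s): ", paste(setdiff(node, nodes), collapse = ", "))
  }
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = nodes))
  out <- as.integer(deg[node])
  names(out) <- node
  out
}

#' @rdname node_degree
#' @export
cross_domain_degree <- function(network, node = NULL) {
  stopifnot(inherits(network, "measure_network"))
  nodes <- network$nodes$name
  if (is.null(node)) node <- nodes
  if (!all(node %in% nodes)) {
    stop("unknown node(s): ", paste(setdiff(node, nodes), collapse = ", "))
  }
  dom <- stats::setNames(network$nodes$domain, network$nodes$name)
  e <- network$edges
  cross <- e[dom[e$from] != dom[e$to], , drop = FALSE]
  deg <- table(factor(c(cross$from, cross$to), levels = nodes))
  out <- as.integer(deg[node])
  names(out) <- node
  out
}

#' Most central nodes by degree
#'
#' All nodes achieving the maximal degree; ties are returned together. With
#' a domain filter, the maximum is taken over that domain's nodes only
#' (their full degree still counts edges to both domains).
#'
#' @param network A nonempty `measure_network`.
#' @param domain Optional `"cognitive"` or `"oculomotor"`.
#' @return Character vector of node names.
#' @export
central_nodes <- function(network, domain = NULL) {
  stopifnot(inherits(network, "measure_network"))
  if (nrow(network$edges) == 0) stop("network has no edges")
  deg <- node_degree(network)
  if (!is.null(domain)) {
    keep <- network$nodes$name[network$nodes$domain == domain]
    deg <- deg[keep]
  }
  names(deg)[deg == max(deg)]
}

#' @export
print.measure_network <- function(x, ...) {
  lab <- if (x$mode == "full") sprintf("full (alpha = %g)", x$param)
         else sprintf("thresholded (|r| > %g)", x$param)
  cat(sprintf("Measure network, %s: %d nodes, %d edges\n",
              lab, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
summary.measure_network <- function(object, ...) {
  deg <- node_degree(object)
  cd <- cross_domain_degree(object)
  out <- data.frame(node = object$nodes$name, domain = object$nodes$domain,
                    degree = deg[object$nodes$name],
                    cross_domain_degree = cd[object$nodes$name],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  print(object)
  ncross <- sum(object$nodes$domain[match(object$edges$from, object$nodes$name)] !=
                object$nodes$domain[match(object$edges$to, object$nodes$name)])
  cat(sprintf("  cross-domain edges: %d; most central: %s\n", ncross,
              if (nrow(object$edges)) paste(central_nodes(object), collapse = ", ")
              else "(none)"))
  invisible(out)
}

#' Convert a measure network to an igraph graph
#'
#' Nodes carry a `domain` attribute; edges carry `weight`, `sign` and
#' `sig_code`.
#'
#' @param network A `measure_network`.
#' @return An undirected `igraph` graph.
#' @export
network_igraph <- function(network) {
  stopifnot(inherits(network, "measure_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Plot a measure network
#'
#' Circular layout with domains grouped; edge width scales with |r| and
#' negative (cross-domain) edges are dashed.
#'
#' @param x A `measure_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.measure_network <- function(x, ...) {
  g <- network_igraph(x)
  cols <- c(cognitive = "#7fb2d5", oculomotor = "#f2a25c")
  igraph::plot.igraph(
    g,
    layout = igraph::layout_in_circle(g),
    vertex.color = cols[igraph::V(g)$domain],
    vertex.label.color = "black",
    edge.width = 1 + 4 * abs(igraph::E(g)$weight),
    edge.lty = ifelse(igraph::E(g)$sign < 0, 2, 1),
    ...)
  invisible(x)
}

#' Export a measure network to disk
#'
#' `graphml` uses the GraphML dialect (via igraph) with node attribute
#' `domain` and edge attributes `weight`, `sign`, `sig_code`; `edgelist` is
#' a tab-separated text file with a node section followed by an edge
#' section. Both formats re-import losslessly through [import_network()].
#'
#' @param network A `measure_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "measure_network"))
  if (format == "graphml") {
    g <- network_igraph(network)
    igraph::graph_attr(g, "mode") <- network$mode
    igraph::graph_attr(g, "param") <- network$param
    igraph::write_graph(g, path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# measure_network\tmode=%s\tparam=%.15g",
                       network$mode, network$param), con)
    writeLines(sprintf("node\t%s\t%s", network$nodes$name,
                       network$nodes$domain), con)
    if (nrow(network$edges)) {
      writeLines(sprintf("edge\t%s\t%s\t%.15g\t%d\t%s",
                         network$edges$from, network$edges$to,
                         network$edges$weight, as.integer(network$edges$sign),
                         network$edges$sig_code), con)
    }
  }
  invisible(path)
}

#' Re-import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return A `measure_network`.
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(name = igraph::V(g)$name,
                        domain = igraph::V(g)$domain,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        weight = if (length(el)) igraph::E(g)$weight else numeric(0),
                        sign = if (length(el)) igraph::E(g)$sign else numeric(0),
                        sig_code = if (length(el)) igraph::E(g)$sig_code else character(0),
                        stringsAsFactors = FALSE)
    mode <- igraph::graph_attr(g, "mode")
    param <- as.numeric(igraph::graph_attr(g, "param"))
  } else {
    lines <- readLines(path)
    hdr <- strsplit(lines[1], "\t")[[1]]
    mode <- sub("^mode=", "", hdr[2])
    param <- as.numeric(sub("^param=", "", hdr[3]))
    body <- lines[-1]
    parts <- strsplit(body, "\t", fixed = TRUE)
    tags <- vapply(parts, `[[`, character(1), 1)
    nd <- parts[tags == "node"]
    ed <- parts[tags == "edge"]
    nodes <- data.frame(name = vapply(nd, `[[`, character(1), 2),
                        domain = vapply(nd, `[[`, character(1), 3),
                        stringsAsFactors = FALSE)
    edges <- data.frame(
      from = vapply(ed, `[[`, character(1), 2),
      to = vapply(ed, `[[`, character(1), 3),
      weight = as.numeric(vapply(ed, `[[`, character(1), 4)),
      sign = as.numeric(vapply(ed, `[[`, character(1), 5)),
      sig_code = vapply(ed, `[[`, character(1), 6),
      stringsAsFactors = FALSE)
  }
  .new_network(nodes, edges, mode, param)
}
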