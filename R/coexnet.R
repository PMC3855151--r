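#' Pairwise Pearson correlations within a group
#'
#' Computes the product-moment correlation for every miRNA pair across
#' the samples of one group, with pairwise-complete observations and a
#' minimum overlap of `min_overlap` samples. Two-sided p-values come from
#' `t = r * sqrt((m - 2) / (1 - r^2))` on `m - 2` degrees of freedom,
#' where `m` is the pair's overlapping sample count.
#'
#' @param x numeric matrix (miRNAs x samples) of log10 expression for the
#'   group's samples, or an `ExpressionMatrix`.
#' @param min_overlap minimum pairwise-complete sample count (default 3).
#' @return List with `r` and `p` (symmetric matrices, `NA` diagonal and
#'   `NA` where undefined) and `m` (overlap counts).
#' @export
pairwise_pearson <- function(x, min_overlap = 3L) {
  if (inherits(x, "ExpressionMatrix")) {
    if (is.null(x$log10_expr)) x <- log_transform(x)
    x <- x$log10_expr
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 3L) stop("need at least 3 samples in the group")
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  m <- tcrossprod(!is.na(x) * 1L)
  r[m < min_overlap] <- NA_real_
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = m - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0        # exact linear relation
  diag(r) <- NA_real_
  diag(p) <- NA_real_
  list(r = r, p = p, m = m)
}

#' Build a coexpression network from correlation matrices
#'
#' An edge connects a miRNA pair when `r >= r_min` and `p < p_max`
#' (positive correlations only by default, a one-sided magnitude
#' criterion; set `use_abs = TRUE` to threshold on
#' `|r|`). The node set contains only endpoints of surviving edges
#' (degree >= 1).
#'
#' @param r,p symmetric correlation and p-value matrices from
#'   [pairwise_pearson()].
#' @param r_min correlation threshold (default 0.79, inclusive).
#' @param p_max p-value threshold (default 0.02, exclusive).
#' @param use_abs threshold on `|r|` instead of `r`? Default `FALSE`.
#' @param group optional group label carried on the network.
#' @return A list of class `CoexNetwork`: `group`, `nodes` (character),
#'   `edges` (data frame `source`, `target`, `r`, `p`, lexicographically
#'   ordered with `source < target`).
#' @export
build_network <- function(r, p, r_min = 0.79, p_max = 0.02,
                          use_abs = FALSE, group = NA_character_) {
  stopifnot(identical(dim(r), dim(p)))
  ids <- rownames(r)
  keep <- !is.na(r) & !is.na(p) & p < p_max &
    (if (use_abs) abs(r) >= r_min else r >= r_min)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx)) {
    a <- ids[idx[, 1L]]; b <- ids[idx[, 2L]]
    src <- pmin(a, b); tgt <- pmax(a, b)
    edges <- data.frame(source = src, target = tgt,
                        r = r[idx], p = p[idx], stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        r = numeric(), p = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(group = group,
                 nodes = sort(unique(c(edges$source, edges$target))),
                 edges = edges),
            class = "CoexNetwork")
}

#' @export
print.CoexNetwork <- function(x, ...) {
  cat(sprintf("CoexNetwork%s: %d nodes, %d edges\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Seed-plus-first-neighbor subnetwork
#'
#' Restricts a network to a seed set of miRNAs (e.g. the PCR-validated
#' signature) and their direct neighbors, keeping the induced edges.
#' Seeds absent from the network are reported and skipped.
#'
#' @param net a `CoexNetwork`.
#' @param seeds character vector of seed miRNA ids.
#' @return A `CoexNetwork` on the seed + first-neighbor node set.
#' @export
first_neighbor_subnetwork <- function(net, seeds) {
  stopifnot(inherits(net, "CoexNetwork"), length(seeds) > 0L)
  absent <- setdiff(seeds, net$nodes)
  if (length(absent))
    message("first_neighbor_subnetwork: seed(s) not in network: ",
            paste(absent, collapse = ", "))
  present <- intersect(seeds, net$nodes)
  e <- net$edges
  touch <- e$source %in% present | e$target %in% present
  nodes <- sort(unique(c(present, e$source[touch], e$target[touch])))
  induced <- e$source %in% nodes & e$target %in% nodes
  out <- net
  out$nodes <- nodes
  out$edges <- e[induced, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

edge_keys <- function(net) paste(net$edges$source, net$edges$target, sep = "|")

#' Compare the edge sets of two networks
#'
#' Set operations on unordered node-pair edge sets (weights ignored for
#' membership): shared links, links unique to each network, and node
#' overlap counts.
#'
#' @param netA,netB `CoexNetwork` objects.
#' @return A list of class `NetworkComparison`: `shared_edges`,
#'   `unique_to_A`, `unique_to_B` (character vectors of `source|target`
#'   keys), `n_shared`, `n_unique_A`, `n_unique_B`, `n_edges_A`,
#'   `n_edges_B`, `n_nodes_shared`, `n_nodes_A`, `n_nodes_B`.
#' @export
compare_networks <- function(netA, netB) {
  stopifnot(inherits(netA, "CoexNetwork"), inherits(netB, "CoexNetwork"))
  ea <- edge_keys(netA); eb <- edge_keys(netB)
  shared <- intersect(ea, eb)
  structure(list(shared_edges = shared,
                 unique_to_A = setdiff(ea, eb),
                 unique_to_B = setdiff(eb, ea),
                 n_shared = length(shared),
                 n_unique_A = length(setdiff(ea, eb)),
                 n_unique_B = length(setdiff(eb, ea)),
                 n_edges_A = length(ea), n_edges_B = length(eb),
                 n_nodes_shared = length(intersect(netA$nodes, netB$nodes)),
                 n_nodes_A = length(netA$nodes),
                 n_nodes_B = length(netB$nodes)),
            class = "NetworkComparison")
}

#' @export
print.NetworkComparison <- function(x, ...) {
  cat(sprintf("NetworkComparison: |E_A| = %d, |E_B| = %d, shared = %d (nodes %d/%d, %d shared)\n",
              x$n_edges_A, x$n_edges_B, x$n_shared,
              x$n_nodes_A, x$n_nodes_B, x$n_nodes_shared))
  invisible(x)
}

#' Export a coexpression network
#'
#' Writes a Cytoscape-readable file: `"sif"` (`source coexp target`
#' rows), `"graphml"` (with `r` and `p` edge attributes, via igraph), or
#' `"tsv"` (edge list `source`, `target`, `r`, `p`). Edges are emitted in
#' stable lexicographic order so repeated exports diff cleanly.
#'
#' @param net a `CoexNetwork`.
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "CoexNetwork"))
  format <- match.arg(format)
  e <- net$edges[order(net$edges$source, net$edges$target), , drop = FALSE]
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$source, "coexp", e$target) else character(),
               path)
  } else if (format == "tsv") {
    out <- data.frame(source = e$source, target = e$target,
                      r = sprintf("%.6g", e$r), p = sprintf("%.6g", e$p),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network export back as a `CoexNetwork`
#'
#' @param path GraphML file written by [export_network()].
#' @param group optional group label.
#' @return A `CoexNetwork`.
#' @export
read_network_graphml <- function(path, group = NA_character_) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(source = pmin(el$from, el$to),
                      target = pmax(el$from, el$to),
                      r = if ("r" %in% names(el)) el$r else NA_real_,
                      p = if ("p" %in% names(el)) el$p else NA_real_,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(group = group,
                 nodes = sort(igraph::V(g)$name),
                 edges = edges),
            class = "CoexNetwork")
}
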