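#' Build the complete pairwise correlation graph
#'
#' Pearson correlations of log2(x + 1)-transformed normalized expression
#' between every unordered pair of molecules in the combined PCG + TE +
#' piRNA panel, giving a complete undirected weighted graph. Zero-variance
#' molecules are dropped with a warning.
#'
#' @param panel numeric matrix, molecules x samples (>= 3 samples).
#' @param kind optional per-molecule kind tags (named by molecule or in row
#'   order).
#' @param log2_transform apply log2(x + 1) before correlating (default TRUE).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return object of class \code{correlation_graph}: list with \code{cor}
#'   (symmetric molecule x molecule matrix, unit diagonal) and \code{kind}.
#' @export
build_correlation_graph <- function(panel, kind = NULL, log2_transform = TRUE,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(panel) < 3) stop("need >= 3 samples", call. = FALSE)
  if (is.null(rownames(panel)))
    rownames(panel) <- paste0("M", seq_len(nrow(panel)))
  if (anyDuplicated(rownames(panel)))
    stop("molecule identifiers must be unique across kinds", call. = FALSE)
  x <- if (log2_transform) log2(panel + 1) else panel
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance molecule(s) dropped")
    x <- x[v > 0, , drop = FALSE]
  }
  if (!is.null(kind)) {
    if (!is.null(names(kind))) kind <- kind[rownames(x)]
    else kind <- kind[v > 0]
    kind <- stats::setNames(as.character(kind), rownames(x))
  }
  cm <- stats::cor(t(x), method = method)
  structure(list(cor = cm, kind = kind), class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  n <- nrow(x$cor)
  cat(sprintf("complete correlation graph: %d molecules, %d edges\n",
              n, n * (n - 1) / 2))
  invisible(x)
}

top_k_neighbors <- function(graph, node, k) {
  r <- graph$cor[node, ]
  r <- r[names(r) != node]
  ord <- order(-abs(r), names(r))     # ties by ascending identifier
  names(r)[ord][seq_len(min(k, length(r)))]
}

#' Extract a seed-centered module
#'
#' Module membership = the seed, its top-k neighbors by absolute
#' correlation, and each such neighbor's own top-k neighbors
#' (neighbors-of-neighbors), merged. Ties in |r| break by ascending
#' identifier, making extraction deterministic and invariant to panel row
#' order.
#'
#' @param graph a [build_correlation_graph()] result.
#' @param seed molecule identifier present in the graph.
#' @param k number of strongest neighbors to follow (>= 1).
#' @return object of class \code{seed_module}: list with \code{seed},
#'   \code{members} (sorted, seed included), \code{k}; edges are attached by
#'   [filter_module_edges()].
#' @export
extract_module <- function(graph, seed, k = 10) {
  stopifnot(inherits(graph, "correlation_graph"), k >= 1)
  if (!seed %in% rownames(graph$cor))
    stop("seed '", seed, "' not in graph", call. = FALSE)
  nb <- top_k_neighbors(graph, seed, k)
  nbnb <- unlist(lapply(nb, top_k_neighbors, graph = graph, k = k))
  members <- sort(unique(c(seed, nb, nbnb)))
  structure(list(seed = seed, members = members, k = k,
                 edges = NULL, threshold = NA_real_),
            class = "seed_module")
}

#' Filter module edges at the third quartile
#'
#' The threshold is the third quartile (linear-interpolation quantile,
#' type 7) of |r| over ALL unordered member pairs — the complete graph on
#' the module nodes, not only the edges that recruited members. Retained
#' edges are the pairs whose |r| strictly exceeds the threshold.
#'
#' @param module a [extract_module()] result.
#' @param graph the [build_correlation_graph()] the module came from.
#' @param use_abs threshold on |r| over all pairs (default, as stated) or on
#'   signed r (sensitivity alternative).
#' @return the module with \code{edges} (data.frame: node1, node2, r) and
#'   \code{threshold} filled in.
#' @export
filter_module_edges <- function(module, graph, use_abs = TRUE) {
  stopifnot(inherits(module, "seed_module"),
            inherits(graph, "correlation_graph"))
  m <- module$members
  if (length(m) < 2) stop("module needs >= 2 members", call. = FALSE)
  pairs <- utils::combn(m, 2)
  r <- graph$cor[cbind(pairs[1, ], pairs[2, ])]
  vals <- if (use_abs) abs(r) else r
  thr <- unname(stats::quantile(vals, 0.75, type = 7))
  keep <- abs(r) > thr
  module$edges <- data.frame(node1 = pairs[1, keep], node2 = pairs[2, keep],
                             r = r[keep], stringsAsFactors = FALSE,
                             row.names = NULL)
  module$threshold <- thr
  module
}

#' @export
print.seed_module <- function(x, ...) {
  cat(sprintf("seed module '%s': %d members (k = %d)", x$seed,
              length(x$members), x$k))
  if (!is.na(x$threshold))
    cat(sprintf(", %d edges above Q3 threshold %.3f", nrow(x$edges),
                x$threshold))
  cat("\n")
  invisible(x)
}

#' Export a module as GraphML, SIF and a members table
#'
#' GraphML carries node attributes \code{kind} and \code{is_seed} and edge
#' attribute \code{r}; SIF lines are \code{node1 cc node2}; the members TSV
#' lists the membership with kinds. Files are named after the seed.
#'
#' @param module a filtered [filter_module_edges()] module.
#' @param graph the source graph (for kind tags).
#' @param dir output directory.
#' @return invisibly, the named vector of written paths.
#' @export
export_module <- function(module, graph, dir) {
  stopifnot(inherits(module, "seed_module"), !is.null(module$edges))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- gsub("[^A-Za-z0-9_.-]", "_", module$seed)
  paths <- c(graphml = file.path(dir, paste0(stem, "_module.graphml")),
             sif = file.path(dir, paste0(stem, "_module.sif")),
             members = file.path(dir, paste0(stem, "_members.tsv")))
  kind <- if (is.null(graph$kind)) rep("molecule", length(module$members)) else
    unname(graph$kind[module$members])
  vertices <- data.frame(name = module$members, kind = kind,
                         is_seed = module$members == module$seed,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(module$edges)) module$edges else
      data.frame(node1 = character(), node2 = character(), r = numeric()),
    directed = FALSE, vertices = vertices)
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  sif <- if (nrow(module$edges))
    paste(module$edges$node1, "cc", module$edges$node2) else character(0)
  writeLines(sif, paths["sif"])
  utils::write.table(cbind(vertices,
                           threshold = module$threshold),
                     paths["members"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
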