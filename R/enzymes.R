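# Steroidogenesis pathway graph and enzyme attribution.  The graph encodes
# the standard biosynthesis routes from cholesterol down to
# mineralocorticoids, glucocorticoids and androgens; each directed edge
# substrate -> product carries the enzyme catalysing the step (ASCII labels:
# P450scc, 3b-HSD, P450C17, 21-hydroxylase, 11b-hydroxylase,
# aldosterone-synthase, sulfotransferase, 17b-HSD, 5a-reductase).  Ratio
# pairs that separate the diagnostic classes are mapped onto the enzymes of
# the pathway route connecting the two steroids; the output is a heuristic
# attribution, not an inference about enzyme activity.

#' Load the steroidogenesis pathway graph
#'
#' Reads a substrate,product,enzyme edge list (one edge per line, CSV with
#' header) into a directed acyclic igraph.  The default is the pathway
#' shipped with the package, which covers all ten panel analytes plus
#' cholesterol, pregnenolone, 17-OH-pregnenolone, 11-deoxycorticosterone
#' and DHT; users can supply an amended file.
#'
#' @param path Edge-list file; default the built-in pathway.
#' @return An igraph object with an `enzyme` edge attribute.
#' @export
steroidogenesis_graph <- function(path = NULL) {
  path <- path %||% .extdata("steroidogenesis_edges.csv")
  edges <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("substrate", "product", "enzyme")
  if (!all(need %in% names(edges)))
    stop("edge list needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(edges$enzyme)))
    stop("every edge must carry an enzyme label", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges[, need], directed = TRUE)
  if (!igraph::is_dag(g))
    stop("pathway graph must be acyclic", call. = FALSE)
  miss <- setdiff(.ANALYTES, igraph::V(g)$name)
  if (length(miss))
    stop("panel analyte(s) absent from pathway graph: ",
         paste(miss, collapse = ", "), call. = FALSE)
  g
}

#' Enzymes connecting two steroids
#'
#' Returns the enzyme labels along the shortest directed pathway route
#' between two steroids, trying first `from -> to`, then `to -> from`.
#' An empty character vector means no directed route exists in either
#' orientation.
#'
#' @param a,b Steroid names (graph nodes).
#' @param graph Pathway graph from [steroidogenesis_graph()].
#' @return Character vector of enzyme labels (possibly empty).
#' @export
#' @examples
#' g <- steroidogenesis_graph()
#' enzymes_for_pair("progesterone", "17-OH-progesterone", g)
enzymes_for_pair <- function(a, b, graph = steroidogenesis_graph()) {
  nodes <- igraph::V(graph)$name
  bad <- setdiff(c(a, b), nodes)
  if (length(bad))
    stop("steroid(s) not in pathway graph: ", paste(bad, collapse = ", "),
         call. = FALSE)
  path_enzymes <- function(from, to) {
    sp <- suppressWarnings(
      igraph::shortest_paths(graph, from, to, mode = "out", output = "epath"))
    ep <- sp$epath[[1]]
    if (length(ep) == 0) NULL else igraph::edge_attr(graph, "enzyme", ep)
  }
  path_enzymes(a, b) %||% path_enzymes(b, a) %||% character(0)
}

#' Rank analyte pairs by between-class log-ratio separation
#'
#' For every unordered analyte pair, the class centroids of the
#' (weight-normalized) log-ratio are computed and the pair's raw
#' separation is the Chebyshev distance between class centroids restricted
#' to that coordinate — i.e. the largest absolute centroid difference over
#' all class pairs.  Raw separations are affinely rescaled per cohort onto
#' the relative 1-100 scale (all-equal separations collapse to the minimal
#' score 1).  Scores are deterministic and invariant to global scaling of
#' any subject's panel.
#'
#' @param cohort A [steroid_cohort()] with complete panels and class
#'   labels.
#' @param weight_normalize Weight-normalize panels first (default TRUE).
#' @return Data frame sorted by descending coefficient: `num`, `den`,
#'   `separation` (raw log-ratio distance), `coefficient` (1-100),
#'   `classes` (the class pair realizing the separation).
#' @export
rank_ratio_separation <- function(cohort, weight_normalize = TRUE) {
  if (anyNA(cohort$class))
    stop("every subject needs a class label", call. = FALSE)
  panels <- cohort_panels(cohort)
  logr <- t(apply(panels, 1, function(row) {
    p <- steroid_panel(row)
    if (weight_normalize) p <- weight_normalize(p)
    log(ratio_vector(p, apply_weight_normalization = FALSE)$r)
  }))
  proto <- ratio_vector(steroid_panel(
    stats::setNames(rep(1, length(.ANALYTES)), .ANALYTES)),
    apply_weight_normalization = FALSE)
  cls <- sort(unique(as.character(cohort$class)))
  centroids <- vapply(cls, function(g)
    colMeans(logr[cohort$class == g, , drop = FALSE]), numeric(ncol(logr)))
  pairs <- utils::combn(cls, 2)
  sep <- numeric(ncol(logr)); which_pair <- character(ncol(logr))
  for (j in seq_len(ncol(logr))) {
    d <- abs(centroids[j, pairs[1, ]] - centroids[j, pairs[2, ]])
    sep[j] <- max(d)
    which_pair[j] <- paste(pairs[, which.max(d)], collapse = "/")
  }
  rng <- range(sep)
  coefficient <- if (diff(rng) == 0) rep(1, length(sep))
                 else pmin(100, pmax(1, 1 + 99 * (sep - rng[1]) / diff(rng)))
  out <- data.frame(num = proto$num, den = proto$den, separation = sep,
                    coefficient = coefficient, classes = which_pair,
                    stringsAsFactors = FALSE)
  out[order(-out$coefficient), , drop = FALSE]
}

#' Select class-discriminating ratio pairs and their enzymes
#'
#' Keeps pairs whose relational coefficient exceeds the threshold
#' (default 40 on the 1-100 scale) and annotates each with the enzymes of
#' the pathway route between its two steroids.
#'
#' @param scores Data frame from [rank_ratio_separation()].
#' @param threshold Coefficient cutoff (pairs strictly above are kept).
#' @param graph Pathway graph used for enzyme annotation.
#' @return The filtered score rows, sorted by descending coefficient, with
#'   an `enzymes` column (`;`-joined labels, empty when no route exists).
#' @export
select_discriminative <- function(scores, threshold = 40,
                                  graph = steroidogenesis_graph()) {
  keep <- scores[scores$coefficient > threshold, , drop = FALSE]
  keep <- keep[order(-keep$coefficient), , drop = FALSE]
  keep$enzymes <- vapply(seq_len(nrow(keep)), function(i)
    paste(enzymes_for_pair(keep$num[i], keep$den[i], graph), collapse = ";"),
    character(1))
  rownames(keep) <- NULL
  keep
}
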