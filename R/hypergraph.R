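#' Hypergraph incidence structure
#'
#' Nodes are subjects; each hyperedge joins a subset of them. The incidence
#' matrix `H` is nodes x hyperedges (0/1, sparse); every hyperedge carries a
#' positive weight and the name of the feature it came from.
#'
#' @param incidence n x E binary matrix (dense or `Matrix` sparse).
#' @param weights positive weight per hyperedge (recycled if length 1).
#' @param provenance source feature name per hyperedge (recycled if
#'   length 1).
#' @return object of class `hypergraph`: `incidence` (sparse dgCMatrix),
#'   `weights`, `provenance`, `n_nodes`, `n_edges`.
#' @export
hypergraph <- function(incidence, weights = 1, provenance = "") {
  H <- methods::as(methods::as(Matrix::Matrix(incidence, sparse = TRUE),
                               "dMatrix"), "CsparseMatrix")
  if (any(H@x != 1)) H@x[] <- 1
  ne <- ncol(H)
  weights <- rep_len(as.numeric(weights), ne)
  provenance <- rep_len(as.character(provenance), ne)
  if (any(weights <= 0))
    stop("hyperedge weights must be > 0", call. = FALSE)
  if (any(Matrix::colSums(H) < 1))
    stop("every hyperedge must contain at least one node", call. = FALSE)
  structure(list(incidence = H, weights = weights, provenance = provenance,
                 n_nodes = nrow(H), n_edges = ne),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d nodes, %d hyperedges from %d feature(s)\n",
              x$n_nodes, x$n_edges, length(unique(x$provenance))))
  invisible(x)
}

#' Categorical hyperedges
#'
#' One hyperedge per observed category, containing exactly the subjects in
#' that category; the hyperedges partition the nodes.
#'
#' @param values categorical column (factor/character/logical/numeric
#'   codes); missing values are an error, never silently dropped.
#' @param feature_name provenance label.
#' @return a [hypergraph()] whose hyperedges partition the node set.
#' @export
build_categorical_hg <- function(values, feature_name = "categorical") {
  if (anyNA(values))
    stop(sprintf("missing values in categorical feature '%s'",
                 feature_name), call. = FALSE)
  v <- as.character(values)
  cats <- sort(unique(v))
  n <- length(v)
  H <- Matrix::sparseMatrix(
    i = seq_len(n),
    j = match(v, cats),
    x = 1, dims = c(n, length(cats)))
  hypergraph(H, weights = 1,
             provenance = rep(feature_name, length(cats)))
}

#' k-uniform nearest-neighbour hyperedges
#'
#' For each node i, one hyperedge containing i itself plus its k-1 nearest
#' neighbours by absolute difference on the (single, typically
#' standardized) feature: exactly n hyperedges, each of size k. Distance
#' ties are broken toward the lower subject index, deterministically.
#'
#' @param values finite continuous column.
#' @param k hyperedge size, `2 <= k <= n`.
#' @param feature_name provenance label.
#' @return a [hypergraph()] with n k-node hyperedges (column j = the
#'   hyperedge seeded at node j).
#' @export
build_knn_uniform_hg <- function(values, k, feature_name = "knn") {
  v <- as.numeric(values)
  n <- length(v)
  k <- as.integer(k)
  if (anyNA(v) || any(!is.finite(v)))
    stop(sprintf("non-finite values in feature '%s'", feature_name),
         call. = FALSE)
  if (k < 2L || k > n)
    stop(sprintf("k must be in [2, n]; got k = %d with n = %d", k, n),
         call. = FALSE)
  members <- matrix(0L, nrow = k, ncol = n)
  idx <- seq_len(n)
  for (i in idx) {
    d <- abs(v - v[i])
    others <- idx[-i]
    ord <- others[order(d[-i], others)]
    members[, i] <- c(i, ord[seq_len(k - 1L)])
  }
  H <- Matrix::sparseMatrix(i = as.vector(members),
                            j = rep(idx, each = k),
                            x = 1, dims = c(n, n))
  hypergraph(H, weights = 1, provenance = rep(feature_name, n))
}

#' Horizontal concatenation of feature hypergraphs
#'
#' Appends the incidence structures of per-feature hypergraphs along the
#' hyperedge axis; every hyperedge takes the ridge-derived weight of the
#' feature it came from, and provenance is retained.
#'
#' @param hypergraphs list of [hypergraph()] objects over the same node
#'   set (same node count and ordering).
#' @param weights named numeric vector: feature name -> weight. Features
#'   absent from `weights` keep weight 1.
#' @return a single combined [hypergraph()].
#' @export
concat_hg <- function(hypergraphs, weights = NULL) {
  stopifnot(length(hypergraphs) >= 1L)
  n <- hypergraphs[[1]]$n_nodes
  for (h in hypergraphs) {
    stopifnot(inherits(h, "hypergraph"))
    if (h$n_nodes != n)
      stop("node counts differ across hypergraphs", call. = FALSE)
  }
  H <- do.call(cbind, lapply(hypergraphs, `[[`, "incidence"))
  prov <- unlist(lapply(hypergraphs, `[[`, "provenance"))
  w <- unlist(lapply(hypergraphs, `[[`, "weights"))
  if (!is.null(weights)) {
    hit <- prov %in% names(weights)
    w[hit] <- weights[prov[hit]]
  }
  hypergraph(H, weights = w, provenance = prov)
}

#' Build per-feature hypergraphs for a feature table
#'
#' Categorical columns (factors, characters, logicals, or numerics with at
#' most two distinct values — the package's 0/1 encodings) become
#' categorical hypergraphs; continuous columns become k-uniform kNN
#' hypergraphs. The per-feature hypergraphs are concatenated with the
#' supplied feature weights.
#'
#' @param x data.frame of features (already standardized where relevant).
#' @param k hyperedge size for continuous features.
#' @param weights named feature weights (e.g. from [ridge_weights()]).
#' @return combined [hypergraph()].
#' @export
build_feature_hypergraphs <- function(x, k, weights = NULL) {
  x <- as.data.frame(x)
  hgs <- lapply(names(x), function(cn) {
    v <- x[[cn]]
    categorical <- is.factor(v) || is.character(v) || is.logical(v) ||
      length(unique(v)) <= 2L
    if (categorical) build_categorical_hg(v, feature_name = cn)
    else build_knn_uniform_hg(v, k = k, feature_name = cn)
  })
  concat_hg(hgs, weights = weights)
}

#' Serialize a hypergraph as coordinate triplets
#'
#' @param hg a [hypergraph()].
#' @return data.frame `node`, `edge`, plus per-edge `weight` and
#'   `provenance` repeated on each triplet (MTX-style long form, suitable
#'   for CSV export).
#' @export
as_triplets <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  tr <- Matrix::summary(hg$incidence)
  data.frame(node = tr$i, edge = tr$j,
             weight = hg$weights[tr$j],
             provenance = hg$provenance[tr$j],
             stringsAsFactors = FALSE)
}
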