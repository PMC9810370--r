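# Connectome embeddings: biased node2vec random walks on the structural
# graph, skip-gram training of node vectors, and the Pearson-similarity
# adjacency built from them.

#' Connectome-embedding configuration
#'
#' Defaults follow the standard node2vec setup for structural connectomes:
#' 100 walks of length 80 per node, return parameter p = 2, in-out parameter
#' q = 1, and 64-dimensional vectors. Skip-gram window, epochs and negative
#' samples are common word2vec defaults and are exposed here.
#'
#' @param dim embedding dimensionality
#' @param walks_per_node number of walks started at every node
#' @param walk_length nodes per walk
#' @param return_p node2vec return parameter p (> 0)
#' @param inout_q node2vec in-out parameter q (> 0)
#' @param window skip-gram context window
#' @param epochs skip-gram training epochs
#' @param negative negative samples per positive pair
#' @param seed integer seed; embedding training is the one stage of the
#'   pipeline that is stochastic by construction, so a seed is mandatory
#' @return an `embedding_config`
#' @export
embedding_config <- function(dim = 64L, walks_per_node = 100L,
                             walk_length = 80L, return_p = 2.0,
                             inout_q = 1.0, window = 10L, epochs = 5L,
                             negative = 5L, seed = 1L) {
  stopifnot(dim >= 2L, walks_per_node >= 1L, walk_length >= 1L,
            return_p > 0, inout_q > 0, window >= 1L, epochs >= 1L,
            negative >= 0L)
  structure(list(dim = as.integer(dim),
                 walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 return_p = return_p, inout_q = inout_q,
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative = as.integer(negative), seed = as.integer(seed)),
            class = "embedding_config")
}

#' Biased second-order random walks on a weighted graph
#'
#' Walk transitions weight each candidate edge w by 1/p when it returns to
#' the previous node, by 1 when the candidate is a neighbor of the previous
#' node, and by 1/q otherwise; weights are renormalized at every step. Walks
#' from isolated nodes terminate immediately (length 1).
#'
#' @param adj a [weighted_adjacency()] or nonnegative matrix
#' @param cfg an [embedding_config()]
#' @return list of integer vectors (1-based node indices), of length
#'   `N * walks_per_node`
#' @export
biased_walks <- function(adj, cfg = embedding_config()) {
  w <- if (inherits(adj, "weighted_adjacency")) adj$weights else as.matrix(adj)
  if (any(w < 0)) stop("walk weights must be nonnegative")
  if (all(w == 0)) stop("all-zero graph: the walk corpus would be empty")
  .cpp_biased_walks(w, cfg$walks_per_node, cfg$walk_length,
                    cfg$return_p, cfg$inout_q, cfg$seed)
}

#' Train node embeddings with the skip-gram model
#'
#' Skip-gram with negative sampling over the walk corpus, single-threaded
#' and fully determined by the seed in `cfg`.
#'
#' @param corpus walk corpus from [biased_walks()]
#' @param n_nodes number of nodes in the graph
#' @param cfg an [embedding_config()]
#' @return a `node_embedding`: list with `vectors` (N x dim matrix, row
#'   order = region order)
#' @export
train_embeddings <- function(corpus, n_nodes, cfg = embedding_config()) {
  if (!length(corpus)) stop("empty walk corpus")
  present <- sort(unique(unlist(corpus)))
  missing <- setdiff(seq_len(n_nodes), present)
  isolated <- logical(n_nodes)
  if (length(missing)) {
    # nodes absent from every walk (cannot happen: every node starts its own
    # walks) would make the skip-gram objective undefined for them
    stop(sprintf("node(s) absent from corpus: %s",
                 paste(missing, collapse = ", ")))
  }
  # a node appearing only in length-1 walks is isolated: its vector is never
  # trained against any context, so flag it for the similarity step
  lens <- vapply(corpus, length, integer(1))
  in_context <- unique(unlist(corpus[lens > 1L]))
  isolated[setdiff(seq_len(n_nodes), in_context)] <- TRUE
  vec <- .cpp_sgns_train(corpus, n_nodes, cfg$dim, cfg$window, cfg$epochs,
                         cfg$negative, 0.025, cfg$seed)
  structure(list(vectors = vec, isolated = isolated),
            class = "node_embedding")
}

#' Pearson-similarity adjacency from node embeddings
#'
#' Entry (n, n') is the Pearson correlation between the two nodes' embedding
#' vectors; the diagonal is set to zero (self-similarity is handled by the
#' walk-order-0 term of the graph filters). Rows of isolated nodes are
#' zeroed rather than left as noise correlations.
#'
#' @param emb a [train_embeddings()] result (or bare N x dim matrix)
#' @return a [weighted_adjacency()] of kind `"CE"`
#' @export
embedding_similarity <- function(emb) {
  vec <- if (inherits(emb, "node_embedding")) emb$vectors else as.matrix(emb)
  if (ncol(vec) < 2L) stop("need at least a 2-dimensional embedding")
  sds <- apply(vec, 1L, stats::sd)
  if (any(sds == 0)) stop("constant embedding row; correlation undefined")
  sim <- stats::cor(t(vec))
  diag(sim) <- 0
  if (inherits(emb, "node_embedding") && any(emb$isolated)) {
    sim[emb$isolated, ] <- 0
    sim[, emb$isolated] <- 0
  }
  weighted_adjacency(sim, "CE")
}

#' One-call connectome embedding pipeline
#'
#' Runs [biased_walks()], [train_embeddings()] and [embedding_similarity()]
#' on a structural adjacency.
#'
#' @param adj a [weighted_adjacency()]
#' @param cfg an [embedding_config()]
#' @return list with `embedding` and `similarity` (the CE adjacency)
#' @export
connectome_embedding <- function(adj, cfg = embedding_config()) {
  n <- nrow(if (inherits(adj, "weighted_adjacency")) adj$weights else adj)
  corpus <- biased_walks(adj, cfg)
  emb <- train_embeddings(corpus, n, cfg)
  list(embedding = emb, similarity = embedding_similarity(emb))
}
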