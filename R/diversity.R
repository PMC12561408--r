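# Diversity gate: identity distances, neighbor-joining trees (via ape),
# Newick I/O, divisive cluster cutting, representative selection and the
# patent-similarity cap.

#' Pairwise identity distance matrix
#'
#' \eqn{d(i,j) = 1 - identity} from [global_align()]; symmetric with zero
#' diagonal by construction.  An optional Jukes-Cantor-style correction for
#' the 20-letter alphabet, \eqn{d' = -\frac{19}{20}\ln(1 - \frac{20}{19}d)},
#' stretches large distances (saturating distances error out).
#'
#' @param records list of >= 2 [peptide_record()]s with unique ids.
#' @param substitution,gap_penalty passed to [global_align()].
#' @param correction `"none"` (p-distance) or `"jc"`.
#' @return symmetric numeric matrix with id dimnames.
#' @export
identity_distance_matrix <- function(records, substitution = NULL,
                                     gap_penalty = 1,
                                     correction = c("none", "jc")) {
  correction <- match.arg(correction)
  n <- length(records)
  stopifnot(n >= 2L)
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("record ids must be unique")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- 1 - alignment_identity(records[[i]], records[[j]],
                                  substitution, gap_penalty)
    d[i, j] <- d[j, i] <- dij
  }
  if (correction == "jc") {
    off <- row(d) != col(d)
    if (any(d[off] >= 19 / 20))
      stop("distance saturates the Jukes-Cantor correction")
    d[off] <- -(19 / 20) * log(1 - (20 / 19) * d[off])
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration (through `ape::nj`) with
#' post-processing: negative branch lengths are clamped to zero and the
#' deficit moved to the sibling branch, so path lengths are preserved as
#' far as possible.  For two taxa a single-edge tree with the distance
#' split evenly is returned.  Additive distance matrices are recovered
#' exactly.
#'
#' @param dm symmetric distance matrix with id dimnames (n >= 2).
#' @return an `ape` `phylo` tree (unrooted; trifurcating root node).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 taxa")
  ids <- rownames(dm)
  if (is.null(ids)) stop("distance matrix must have id dimnames")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = rep(dm[1, 2] / 2, 2L),
               tip.label = ids, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dm))
  clamp_negative_branches(tr)
}

# clamp negative branch lengths to zero, moving the deficit to a sibling
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0L) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs))
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Newick serialization
#'
#' Thin wrappers over `ape` adding the interchange conventions used here:
#' leaf labels containing spaces or Newick metacharacters are quoted on
#' write and unquoted on read; duplicate leaf labels and malformed text
#' are errors.
#'
#' @param tree a `phylo` tree.
#' @param path optional file path; if `NULL`, the Newick string is
#'   returned/parsed directly.
#' @param text Newick string (alternative to `path`).
#' @return `write_newick()`: the Newick string, invisibly if written to a
#'   file; `read_newick()`: a `phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  tr <- tree
  need <- which(grepl("[][ (),:;']", tr$tip.label))
  orig <- tr$tip.label[need]
  ph <- sprintf("PFNWK%dX", seq_along(need))
  tr$tip.label[need] <- ph
  txt <- ape::write.tree(tr, digits = 10)
  for (i in seq_along(need))   # quoted originals back in place
    txt <- sub(ph[i], paste0("'", gsub("'", "''", orig[i]), "'"),
               txt, fixed = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "")
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close) stop("unbalanced parentheses in Newick text")
  # shelter quoted labels from the parser behind placeholders
  qpat <- "'(?:[^']|'')*'"
  quoted <- regmatches(text, gregexpr(qpat, text))[[1]]
  ph <- sprintf("PFNWK%dX", seq_along(quoted))
  for (i in seq_along(quoted))
    text <- sub(quoted[i], ph[i], text, fixed = TRUE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick text")
  hit <- match(tr$tip.label, ph)
  restore <- !is.na(hit)
  tr$tip.label[restore] <-
    gsub("''", "'", sub("^'(.*)'$", "\\1", quoted[hit[restore]]))
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels")
  tr
}

#' Cut a tree into k leaf clusters
#'
#' Greedy divisive edge removal: edges are visited longest-first (ties by
#' canonical child-node order) and an edge is removed only if the removal
#' increases the number of connected leaf components, until `k` components
#' exist.  Clusters at `k + 1` therefore refine clusters at `k`; `k = 1`
#' returns a single cluster and `k = n` singletons.
#'
#' @param tree a `phylo` tree.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return object of class `cluster_set`: list with `clusters` (named list
#'   of leaf-id vectors), `k`, `method`.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  nodes <- max(tree$edge)
  comp_count <- function(removed) {
    parent <- seq_len(nodes)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in seq_len(nrow(tree$edge))) {
      if (removed[e]) next
      a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
      if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_len(n), find, integer(1))
    list(n = length(unique(comp)), comp = comp)
  }
  ord <- order(-tree$edge.length, tree$edge[, 2])
  removed <- rep(FALSE, nrow(tree$edge))
  cur <- comp_count(removed)
  for (e in ord) {
    if (cur$n >= k) break
    removed[e] <- TRUE
    nxt <- comp_count(removed)
    if (nxt$n > cur$n) cur <- nxt else removed[e] <- FALSE
  }
  comp <- cur$comp
  clusters <- split(tree$tip.label, comp)
  names(clusters) <- paste0("C", seq_along(clusters))
  structure(list(clusters = clusters, k = k, method = "longest-edge"),
            class = "cluster_set")
}

#' Select one representative per cluster
#'
#' Deterministic rules: `max_recovery` keeps the member with the highest
#' recovery value; `medoid` keeps the member minimizing the total distance
#' to its cluster mates; `first` keeps the lexicographically first id.
#' All ties break lexicographically by id.
#'
#' @param clusters a [cut_clusters()] result or a list of id vectors.
#' @param rule selection rule.
#' @param recovery named numeric vector of recovery values (for
#'   `max_recovery`).
#' @param dist distance matrix with id dimnames (for `medoid`).
#' @return character vector of selected ids, one per cluster.
#' @export
select_representatives <- function(clusters,
                                   rule = c("max_recovery", "medoid",
                                            "first"),
                                   recovery = NULL, dist = NULL) {
  rule <- match.arg(rule)
  if (inherits(clusters, "cluster_set")) clusters <- clusters$clusters
  vapply(clusters, function(ids) {
    if (length(ids) == 0L) stop("empty cluster")
    ids <- sort(ids)
    switch(rule,
           first = ids[1],
           max_recovery = {
             if (is.null(recovery) || !all(ids %in% names(recovery)))
               stop("recovery values required for every cluster member")
             ids[which.max(recovery[ids])]
           },
           medoid = {
             if (is.null(dist) || !all(ids %in% rownames(dist)))
               stop("distance matrix required for every cluster member")
             tot <- rowSums(dist[ids, ids, drop = FALSE])
             ids[which.min(tot)]
           })
  }, character(1), USE.NAMES = FALSE)
}

#' Patent-similarity gate
#'
#' Fails a candidate whose global-alignment identity to the reference
#' (marketed) sequence is at or above the cap, so the reference itself
#' fails at every cap <= 1 (identity 1 >= cap).
#'
#' @param record candidate [peptide_record()].
#' @param reference reference [peptide_record()] (e.g. the template drug).
#' @param max_identity identity cap in (0, 1].
#' @return a `gate_result`.
#' @export
patent_gate <- function(record, reference, max_identity = 0.9) {
  stopifnot(max_identity > 0, max_identity <= 1)
  ident <- alignment_identity(record, reference)
  reasons <- NULL
  if (ident >= max_identity)
    reasons <- add_reason(reasons, "patent_identity", signif(ident, 4),
                          paste0("< ", max_identity))
  gate_result(reasons)
}

#' Path distance between two leaves
#'
#' Sum of branch lengths on the unique path between leaves `a` and `b`.
#'
#' @param tree a `phylo` tree.
#' @param a,b leaf labels.
#' @return nonnegative numeric.
#' @export
tree_distance <- function(tree, a, b) {
  miss <- setdiff(c(a, b), tree$tip.label)
  if (length(miss)) stop("unknown leaf label(s): ", paste(miss, collapse = ", "))
  if (a == b) return(0)
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  d <- ape::dist.nodes(tree)
  d[ia, ib]
}
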