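# Exact and approximate 2-nearest-neighbour search over descriptors:
# a KD-tree queried best-bin-first under a leaf-visit budget, plus the
# exhaustive-scan oracle.  All distances are Euclidean; every tie is
# broken towards the lower descriptor index so results are deterministic.

#' Build a KD-tree over descriptor rows
#'
#' Each node splits on the dimension of maximum spread among its points,
#' at the median (points are ordered by coordinate with index tie-break
#' and the lower half, rounded up, goes left; the split value is the
#' largest left-side coordinate).  Leaves hold one descriptor index each,
#' so the best-bin-first budget counts descriptors examined.
#'
#' @param data numeric matrix, one descriptor per row, `n >= 2`.
#' @return object of class `"kdtree"`: parallel node arrays `split_dim`,
#'   `split_val`, `left`, `right`, `point` (0 where not applicable,
#'   indices 1-based, root = node 1) plus the `data` matrix.
#' @export
build_kdtree <- function(data) {
  if (!is.matrix(data)) data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2) stop("need at least 2 descriptors; use brute_force_knn for fewer")
  n_nodes <- 2L * n - 1L
  split_dim <- integer(n_nodes); split_val <- numeric(n_nodes)
  left <- integer(n_nodes); right <- integer(n_nodes); point <- integer(n_nodes)
  next_id <- 0L
  rec <- function(idx) {
    next_id <<- next_id + 1L
    id <- next_id
    if (length(idx) == 1L) {
      point[id] <<- idx
      return(id)
    }
    sub <- data[idx, , drop = FALSE]
    spread <- apply(sub, 2, function(v) max(v) - min(v))
    dim <- which.max(spread)  # ties -> lowest dimension
    ord <- idx[order(data[idx, dim], idx)]
    nl <- ceiling(length(ord) / 2)
    split_dim[id] <<- dim
    split_val[id] <<- data[ord[nl], dim]
    left[id] <<- rec(ord[seq_len(nl)])
    right[id] <<- rec(ord[seq.int(nl + 1L, length(ord))])
    id
  }
  rec(seq_len(n))
  structure(list(split_dim = split_dim, split_val = split_val,
                 left = left, right = right, point = point,
                 n_points = n, data = data),
            class = "kdtree")
}

#' @export
print.kdtree <- function(x, ...) {
  cat("KD-tree over", x$n_points, "descriptors of dimension",
      ncol(x$data), "\n")
  invisible(x)
}

#' Leaf indices of a KD-tree in in-order traversal
#'
#' Mostly useful for checking that every stored descriptor is reachable
#' exactly once.
#'
#' @param tree a `"kdtree"`.
#' @return integer vector of descriptor indices.
#' @export
kdtree_indices <- function(tree) {
  out <- integer(0)
  rec <- function(id) {
    if (tree$point[id] > 0L) { out[length(out) + 1L] <<- tree$point[id]; return() }
    rec(tree$left[id]); rec(tree$right[id])
  }
  rec(1L)
  out
}

#' Best-bin-first approximate 2-nearest-neighbour search
#'
#' Searches the KD-tree with a priority queue keyed on the axis distance
#' to each node's unexplored half-space, stopping when the queue empties
#' or `node_budget` leaves have been examined (a deterministic budget in
#' place of the wall-clock cut-off sometimes used, which is untestable).  With
#' `node_budget >= n` the search is exact and agrees with
#' [brute_force_knn()] down to tie-breaks.
#'
#' @param tree a `"kdtree"`.
#' @param query numeric vector, or matrix of query rows.
#' @param k number of neighbours; only `k = 2` is supported.
#' @param node_budget leaf-visit budget (default 200).
#' @return data frame with one row per query: nearest index `q`, second
#'   index `q2`, distances `d1 <= d2`, and `leaves` examined.
#' @export
bbf_knn <- function(tree, query, k = 2L, node_budget = 200) {
  stopifnot(inherits(tree, "kdtree"))
  if (k != 2L) stop("only k = 2 is supported")
  if (tree$n_points < 2) stop("tree must hold at least 2 descriptors")
  if (!is.matrix(query)) query <- matrix(query, nrow = 1)
  res <- cpp_bbf_knn2(tree$split_dim, tree$split_val, tree$left, tree$right,
                      tree$point, tree$data, query,
                      if (is.finite(node_budget)) node_budget else .Machine$integer.max)
  data.frame(q = as.integer(res[, 1]), q2 = as.integer(res[, 2]),
             d1 = res[, 3], d2 = res[, 4], leaves = as.integer(res[, 5]))
}

#' Exact 2-nearest-neighbour search by full scan
#'
#' The enumeration oracle for [bbf_knn()]: identical distance arithmetic
#' and tie-break rule, no tree, no budget.
#'
#' @param data numeric matrix of stored descriptors, `n >= 2`.
#' @param query numeric vector or matrix of query rows.
#' @param k number of neighbours; only `k = 2` is supported.
#' @return data frame with columns `q`, `q2`, `d1`, `d2`.
#' @export
brute_force_knn <- function(data, query, k = 2L) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (k != 2L) stop("only k = 2 is supported")
  if (nrow(data) < 2) stop("need at least 2 descriptors")
  if (!is.matrix(query)) query <- matrix(query, nrow = 1)
  res <- cpp_brute_knn2(data, query)
  data.frame(q = as.integer(res[, 1]), q2 = as.integer(res[, 2]),
             d1 = res[, 3], d2 = res[, 4])
}

#' Match descriptors of one image against another
#'
#' For every row of `desc_from`, finds its nearest and second-nearest
#' neighbour among the rows of `desc_to`.
#'
#' @param desc_from,desc_to descriptor matrices.
#' @param method `"bbf"` (KD-tree best-bin-first) or `"brute"` (exact).
#' @param node_budget BBF leaf budget (default 200).
#' @return data frame with columns `p` (query index), `q`, `q2`, `d1`,
#'   `d2`.
#' @export
match_descriptors <- function(desc_from, desc_to, method = c("bbf", "brute"),
                              node_budget = 200) {
  method <- match.arg(method)
  if (nrow(desc_from) == 0 || nrow(desc_to) < 2)
    return(data.frame(p = integer(), q = integer(), q2 = integer(),
                      d1 = numeric(), d2 = numeric()))
  nn <- if (method == "bbf")
    bbf_knn(build_kdtree(desc_to), desc_from, node_budget = node_budget)
  else brute_force_knn(desc_to, desc_from)
  data.frame(p = seq_len(nrow(desc_from)), q = nn$q, q2 = nn$q2,
             d1 = nn$d1, d2 = nn$d2)
}
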