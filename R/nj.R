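#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler selection
#' criterion. Ties in the selection criterion are broken by the lowest
#' pair index (row-major over the current node ordering), which makes the
#' result deterministic and invariant to input permutation up to topology.
#' For additive distances the original tree (topology and branch lengths)
#' is recovered exactly. Negative branch lengths can optionally be clamped
#' to zero with the deficit moved onto the sister branch; clamping is off
#' by default and the number of clamped branches is recorded in the
#' `n_clamped` attribute.
#'
#' @param d symmetric numeric distance matrix with at least 3 labelled
#'   rows/columns.
#' @param clamp_negative clamp negative branch lengths?
#' @return an unrooted `phylo` tree (basal trifurcation), serializable
#'   with [ape::write.tree()].
#' @export
neighbor_joining <- function(d, clamp_negative = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 samples")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- rownames(d)
  # node keys: 1..n tips, then n+1, n+2, ... internals in creation order
  active <- seq_len(n)
  D <- d
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  next_key <- n + 1L
  n_clamped <- 0L
  clamp <- function(li, lj, dij) {
    if (!clamp_negative) return(c(li, lj))
    if (li < 0) { n_clamped <<- n_clamped + 1L; li <- 0; lj <- dij }
    else if (lj < 0) { n_clamped <<- n_clamped + 1L; lj <- 0; li <- dij }
    c(li, lj)
  }
  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf  # consider i < j only; which.min is row-major
    best <- which(Q == min(Q), arr.ind = TRUE)
    # lowest pair index tie-break: smallest i, then smallest j
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    ll <- clamp(li, lj, dij)
    u <- next_key; next_key <- next_key + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, ll[1], ll[2])
    du <- (D[i, ] + D[j, ] - dij) / 2
    D <- rbind(cbind(D, du), c(du, 0))
    keep <- setdiff(seq_len(r + 1), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    active <- c(active, u)[keep]
  }
  # final trifurcation by the three-point formulas
  v <- next_key
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  if (clamp_negative) {
    neg <- c(l1, l2, l3) < 0
    n_clamped <- n_clamped + sum(neg)
    l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  }
  edges <- rbind(edges, c(v, active[1]), c(v, active[2]), c(v, active[3]))
  lens <- c(lens, l1, l2, l3)

  # renumber internals in preorder from the final node so root = n+1
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  newnum <- integer(next_key)
  newnum[seq_len(n)] <- seq_len(n)
  counter <- n
  edge_out <- matrix(0L, nrow(edges), 2)
  len_out <- numeric(nrow(edges))
  pos <- 0L
  visit <- function(key) {
    counter <<- counter + 1L
    newnum[key] <<- counter
    for (e in kids[[as.character(key)]]) {
      child <- edges[e, 2]
      pos <<- pos + 1L
      row <- pos
      if (child > n) visit(child)
      edge_out[row, ] <<- c(newnum[key], newnum[child])
      len_out[row] <<- lens[e]
    }
  }
  visit(v)
  tree <- structure(list(edge = edge_out, edge.length = len_out,
                         tip.label = labels, Nnode = n - 2L),
                    class = "phylo", order = "cladewise",
                    n_clamped = n_clamped)
  tree
}
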