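# Alpha/beta diversity, principal coordinates analysis, and a deterministic
# Saitou-Nei neighbor-joining implementation with Newick output.

#' Alpha diversity of an abundance profile
#'
#' Shannon index uses the natural logarithm (with `0 log 0 := 0`); Simpson
#' index is `1 - sum(p^2)`.
#'
#' @param profile An [profile_abundance()] result, or a numeric vector of
#'   relative abundances summing to 1.
#' @return List with `shannon`, `simpson`, `richness`.
#' @export
alpha_diversity <- function(profile) {
  p <- if (is.data.frame(profile)) profile$relative_abundance else profile
  if (!length(p) || abs(sum(p) - 1) > 1e-6 || any(p < 0))
    stop("profile abundances must be non-negative and sum to 1")
  pp <- p[p > 0]
  list(shannon = -sum(pp * log(pp)),
       simpson = 1 - sum(p^2),
       richness = length(pp))
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' Computed over the union of species: `sum(|x - y|) / sum(x + y)`.
#'
#' @param p1,p2 [profile_abundance()] results or named abundance vectors.
#' @return Dissimilarity in `[0, 1]`, `NA` (with warning) if both profiles
#'   are empty.
#' @export
bray_curtis <- function(p1, p2) {
  v <- profile_vectors(p1, p2)
  tot <- sum(v$x + v$y)
  if (tot == 0) {
    warning("both profiles empty; Bray-Curtis undefined")
    return(NA_real_)
  }
  sum(abs(v$x - v$y)) / tot
}

profile_vectors <- function(p1, p2) {
  as_vec <- function(p) {
    if (is.data.frame(p)) stats::setNames(p$relative_abundance, p$species)
    else p
  }
  a <- as_vec(p1); b <- as_vec(p2)
  sp <- sort(unique(c(names(a), names(b))))
  x <- a[sp]; y <- b[sp]
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  list(x = unname(x), y = unname(y), species = sp)
}

#' Pairwise Bray-Curtis matrix over samples
#'
#' @param profiles Named list of abundance profiles.
#' @return Symmetric matrix of dissimilarities with zero diagonal.
#' @export
beta_matrix <- function(profiles) {
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- bray_curtis(profiles[[i]], profiles[[j]])
  }
  m
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared-distance (Gower) matrix, takes the top-`k`
#' eigenvectors scaled by the square root of their eigenvalues, and reports
#' explained-variance fractions over the positive eigenvalues only
#' (negative eigenvalues are dropped from the denominator).
#'
#' @param d Symmetric distance matrix (e.g. from [beta_matrix()]).
#' @param k Number of dimensions requested.
#' @return List with `points` (samples x k matrix), `eig` (positive
#'   eigenvalues) and `explained` (variance fractions for the returned
#'   axes). `k` exceeding the number of positive eigenvalues is truncated
#'   with a warning.
#' @export
pcoa <- function(d, k = 2L) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), isSymmetric(unname(d)))
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(abs(e$values)) * 1e-9)
  if (!length(pos)) {  # degenerate (e.g. all-zero) matrix: flat embedding
    pts <- matrix(0, n, k, dimnames = list(rownames(d),
                                           paste0("PCo", seq_len(k))))
    return(list(points = pts, eig = numeric(0),
                explained = rep(0, k)))
  }
  if (k > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); truncating k")
    k <- length(pos)
  }
  sel <- pos[seq_len(k)]
  pts <- e$vectors[, sel, drop = FALSE] %*% diag(sqrt(e$values[sel]), k, k)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eig = e$values[pos],
       explained = e$values[sel] / sum(e$values[pos]))
}

#' Neighbor-joining tree with Newick output
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (equal Q
#' values resolve to the lexicographically smallest pair of node labels,
#' a node being labelled by the smallest leaf beneath it). Negative branch
#' lengths are clamped to zero with the deficit moved to the adjacent
#' branch. Exact on additive distance matrices.
#'
#' @param dm Symmetric distance matrix.
#' @param labels Taxon labels (default from `dm` dimnames).
#' @return A Newick string (rooted representation of the unrooted tree:
#'   trifurcating root for >= 3 taxa).
#' @export
nj_tree <- function(dm, labels = rownames(dm)) {
  dm <- as.matrix(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dm)))
  if (!isTRUE(all.equal(unname(dm), unname(t(dm)))))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  stopifnot(n >= 2L, length(labels) == n)
  newick <- labels        # growing subtree strings
  minlab <- labels        # smallest leaf label beneath each node
  D <- dm
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(minlab[ij[1]], minlab[ij[2]])); paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(bi), newick[j], fmt(bj))
    new_min <- min(minlab[i], minlab[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    newick <- c(newick[keep], new_nwk)
    minlab <- c(minlab[keep], new_min)
  }
  if (nrow(D) == 2L) {
    b <- D[1, 2] / 2
    return(sprintf("(%s:%s,%s:%s);", newick[1], fmt(b), newick[2], fmt(b)))
  }
  # terminal 3-star
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  sprintf("(%s:%s,%s:%s,%s:%s);",
          newick[1], fmt(b[1]), newick[2], fmt(b[2]), newick[3], fmt(b[3]))
}
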