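#' Row-normalize a similarity matrix into a transition matrix
#'
#' `W = D^-1 S` with `D_ii = sum_j S_ij`; each row of W sums to 1.
#' A zero row cannot arise from a valid similarity matrix (unit diagonal)
#' but is guarded against anyway.
#'
#' @param S a `similarity_matrix` or a nonnegative square matrix.
#' @return the row-stochastic matrix W.
#' @export
row_normalize <- function(S) {
  V <- if (inherits(S, "similarity_matrix")) S$values else as.matrix(S)
  if (min(V) < 0) stop("similarity matrix must be nonnegative")
  deg <- rowSums(V)
  if (any(deg == 0))
    stop("zero-degree row(s): ", paste(which(deg == 0), collapse = ", "))
  V / deg
}

#' Random walk with restart over a transition matrix
#'
#' From every start node i, iterates
#' `p_t = alpha * p_{t-1} W + (1 - alpha) * e_i` from `p_0 = e_i` until
#' the L1 change drops below `epsilon`. All m walks are propagated
#' together as one matrix iteration (`P_t = alpha P_{t-1} W + (1-alpha) I`),
#' which is identical per row; convergence is the max over rows of the L1
#' change, i.e. the strictest per-row criterion. Row i of the result is
#' the diffusion state of drug i.
#'
#' @param W row-stochastic matrix from [row_normalize()].
#' @param alpha restart probability in (0,1).
#' @param epsilon L1 convergence tolerance (> 0).
#' @param max_iter iteration cap; with alpha < 1 convergence is geometric,
#'   so the cap only catches non-finite pathologies.
#' @return a `diffusion_matrix`: list with row-stochastic `values`,
#'   `iterations`, `alpha`, `epsilon`.
#' @export
rwr <- function(W, alpha = 0.8, epsilon = 1e-9, max_iter = 1000L) {
  W <- as.matrix(W)
  stopifnot(alpha > 0, alpha < 1, epsilon > 0)
  if (max(abs(rowSums(W) - 1)) > 1e-8) stop("W must be row-stochastic")
  m <- nrow(W)
  restart <- diag(1 - alpha, m)
  P <- diag(m)
  for (it in seq_len(max_iter)) {
    P_new <- alpha * (P %*% W) + restart
    delta <- max(rowSums(abs(P_new - P)))
    P <- P_new
    if (!is.finite(delta)) stop("non-finite diffusion at iteration ", it)
    if (delta < epsilon) {
      dimnames(P) <- dimnames(W)
      return(structure(list(values = P, iterations = it,
                            alpha = alpha, epsilon = epsilon),
                       class = "diffusion_matrix"))
    }
  }
  stop("random walk did not converge within ", max_iter,
       " iterations (last L1 residual ", format(delta), ")")
}

#' Positive pointwise mutual information of a diffusion matrix
#'
#' `X(i,j) = max(0, log2( P(i,j) * T / (r_i * c_j) ))` with T the grand
#' sum, `r_i` the row sum and `c_j` the column sum; cells with
#' `P(i,j) = 0` map to 0. Measures how much more often the walk from i
#' visits j than expected under independence of the marginals.
#'
#' @param P a `diffusion_matrix` or a nonnegative matrix with positive
#'   total mass.
#' @return the nonnegative PPMI matrix X (generally asymmetric).
#' @export
ppmi <- function(P) {
  V <- if (inherits(P, "diffusion_matrix")) P$values else as.matrix(P)
  if (min(V) < 0) stop("PPMI input must be nonnegative")
  total <- sum(V)
  if (total <= 0) stop("PPMI input must have positive total mass")
  r <- rowSums(V)
  cs <- colSums(V)
  ratio <- V * total / outer(r, cs)
  X <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
  pos <- V > 0
  X[pos] <- pmax(0, log2(ratio[pos]))
  X
}

#' Symmetrize a topological-similarity matrix by averaging
#'
#' `N(i,j) = (X(i,j) + X(j,i)) / 2`, making the network exactly symmetric.
#'
#' @param X square matrix.
#' @param source_name label carried on the result.
#' @return a `ppmi_network`: list with symmetric nonnegative `values`.
#' @export
symmetrize <- function(X, source_name = "network") {
  X <- as.matrix(X)
  stopifnot(nrow(X) == ncol(X))
  N <- (X + t(X)) / 2
  structure(list(source_name = source_name, values = N),
            class = "ppmi_network")
}

#' Topological-similarity network from one similarity matrix
#'
#' Composition of the diffusion stages: row-normalize, random walk with
#' restart, PPMI, symmetrize. One call per similarity source yields the
#' networks N1..N5 that feed the autoencoder.
#'
#' @param S a `similarity_matrix`.
#' @param alpha,epsilon see [rwr()].
#' @return a `ppmi_network`.
#' @export
topological_similarity <- function(S, alpha = 0.8, epsilon = 1e-9) {
  stopifnot(inherits(S, "similarity_matrix"))
  P <- rwr(row_normalize(S), alpha = alpha, epsilon = epsilon)
  symmetrize(ppmi(P), source_name = S$source_name)
}

#' Build every topological network from a set of similarity matrices
#'
#' @param sims named list of `similarity_matrix` objects.
#' @param alpha,epsilon see [rwr()].
#' @return named list of `ppmi_network` objects, same order as `sims`.
#' @export
build_all_networks <- function(sims, alpha = 0.8, epsilon = 1e-9) {
  lapply(sims, topological_similarity, alpha = alpha, epsilon = epsilon)
}
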