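#' Continuous-time kinetic model of a multi-state FRET system
#'
#' A `kinetic_model` bundles the quantities that define the photon-level
#' generative model of a conformationally switching molecule: the number of
#' states `K`, one FRET efficiency per state, and a conservative rate matrix
#' `Q` (s^-1) whose off-diagonal entry `Q[i, j]` is the transition rate from
#' state `i` to state `j`. The stationary distribution is computed on
#' construction and cached in the object.
#'
#' @param E Numeric vector of per-state FRET efficiencies, each in \[0, 1\].
#' @param Q Square rate matrix in s^-1. Off-diagonal entries must be
#'   non-negative and each row must sum to zero (diagonal may be omitted by
#'   passing rows summing to anything; it is then reset to minus the
#'   off-diagonal row sum).
#' @param connectivity Optional logical matrix marking allowed transitions.
#'   Defaults to `Q != 0` off the diagonal. Disallowed entries of `Q` must be
#'   exactly zero.
#'
#' @return An object of class `kinetic_model` with elements `K`, `E`, `Q`,
#'   `pi` (stationary occupancies) and `connectivity`.
#' @examples
#' m <- kinetic_model(E = c(0.8, 0.2), Q = rate_matrix_chain(c(0.8, 0.2),
#'   k_fwd = 1000, k_bwd = 1500))
#' m$pi
#' @export
kinetic_model <- function(E, Q, connectivity = NULL) {
  E <- as.numeric(E)
  K <- length(E)
  stopifnot(K >= 1)
  if (any(!is.finite(E)) || any(E < 0) || any(E > 1)) {
    stop("state efficiencies must be finite and in [0, 1]")
  }
  Q <- as.matrix(Q)
  if (nrow(Q) != K || ncol(Q) != K) {
    stop("Q must be a ", K, "x", K, " matrix to match length(E)")
  }
  offdiag <- Q
  diag(offdiag) <- 0
  if (any(offdiag < 0)) {
    bad <- which(offdiag < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative off-diagonal rate Q[%d,%d]: rate matrices must have non-negative transition rates", bad[1], bad[2]))
  }
  diag(Q) <- -rowSums(offdiag)
  if (is.null(connectivity)) {
    connectivity <- offdiag > 0
  } else {
    connectivity <- as.matrix(connectivity)
    stopifnot(dim(connectivity) == c(K, K))
    diag(connectivity) <- FALSE
    if (any(offdiag[!connectivity] != 0)) {
      stop("Q has non-zero rates on transitions disallowed by the connectivity mask")
    }
  }
  pi <- if (K == 1) 1 else stationary_distribution(Q)
  structure(
    list(K = K, E = E, Q = Q, pi = pi, connectivity = connectivity),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %d state(s)\n", x$K))
  cat("  E :", paste(sprintf("%.3f", x$E), collapse = "  "), "\n")
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = "  "), "\n")
  if (x$K > 1) {
    cat("  rates (s^-1):\n")
    print(round(x$Q, 1))
  }
  invisible(x)
}

#' Build the rate matrix of a sequential (chain) kinetic scheme
#'
#' States exchange only with their neighbours along the chain
#' (1 <-> 2 <-> ... <-> K), the connectivity found to describe M-domain
#' switching. `k_fwd[i]` is the i -> i+1 rate, `k_bwd[i]` the i+1 -> i rate.
#'
#' @param E Per-state efficiencies (only the length is used).
#' @param k_fwd,k_bwd Forward and backward rate vectors of length `K - 1`, s^-1.
#' @return A `K x K` conservative rate matrix.
#' @export
rate_matrix_chain <- function(E, k_fwd, k_bwd) {
  K <- length(E)
  stopifnot(length(k_fwd) == K - 1, length(k_bwd) == K - 1)
  Q <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    Q[i, i + 1] <- k_fwd[i]
    Q[i + 1, i] <- k_bwd[i]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Three-state M-domain kinetic model (wild-type, ATP conditions)
#'
#' The sequential three-state model describing wild-type ClpB M-domain
#' dynamics: FRET efficiencies 0.8 / 0.47 / 0.15 and interconversion rates
#' k12 = 5300, k21 = 5700, k23 = 800, k32 = 2300 s^-1. State 1 (high E) is
#' the active, tilted conformation; state 2 the inactive, parallel one;
#' state 3 a minor low-E state.
#'
#' @return A `kinetic_model`.
#' @export
wt_mdomain_model <- function() {
  kinetic_model(
    E = c(0.80, 0.47, 0.15),
    Q = rate_matrix_chain(c(0.80, 0.47, 0.15),
                          k_fwd = c(5300, 800),
                          k_bwd = c(5700, 2300))
  )
}

#' Stationary distribution of a conservative rate matrix
#'
#' Solves pi Q = 0 with sum(pi) = 1 by a dense linear solve of the
#' replaced-column system; the chain must be irreducible on its non-zero
#' transition graph.
#'
#' @param Q Conservative rate matrix (rows sum to 0, off-diagonals >= 0).
#' @return Numeric vector of stationary occupancies.
#' @examples
#' stationary_distribution(rate_matrix_chain(1:2, 1000, 1000))
#' @export
stationary_distribution <- function(Q) {
  Q <- as.matrix(Q)
  K <- nrow(Q)
  stopifnot(ncol(Q) == K)
  offdiag <- Q
  diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal rates must be non-negative")
  if (max(abs(rowSums(Q))) > 1e-8 * max(abs(Q), 1)) {
    stop("Q is not conservative: rows must sum to zero")
  }
  if (K == 1) return(1)
  comp <- .reachability_components(offdiag > 0)
  if (max(comp) > 1) {
    stop("rate matrix is reducible; disconnected state groups: ",
         paste(vapply(seq_len(max(comp)),
                      function(g) paste0("{", paste(which(comp == g), collapse = ","), "}"),
                      character(1)),
               collapse = " "))
  }
  # pi Q = 0, replace one balance equation with the normalization constraint
  A <- t(Q)
  A[K, ] <- 1
  b <- c(rep(0, K - 1), 1)
  pi <- solve(A, b)
  pi[abs(pi) < 1e-15] <- 0
  pi / sum(pi)
}

# connected components of the undirected transition graph
.reachability_components <- function(adj) {
  K <- nrow(adj)
  adj <- adj | t(adj)
  comp <- rep(0L, K)
  g <- 0L
  for (s in seq_len(K)) {
    if (comp[s]) next
    g <- g + 1L
    frontier <- s
    comp[s] <- g
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nxt] <- g
      frontier <- nxt
    }
  }
  comp
}

#' Reorder a kinetic model's states by descending FRET efficiency
#'
#' The canonical presentation used throughout: state 1 is the highest-E
#' (active) state, matching the field's labeling of the M-domain states.
#'
#' @param model A `kinetic_model`.
#' @return The model with states permuted into canonical order.
#' @export
canonical_order <- function(model) {
  ord <- order(model$E, decreasing = TRUE)
  if (all(ord == seq_len(model$K))) return(model)
  kinetic_model(model$E[ord], model$Q[ord, ord, drop = FALSE],
                model$connectivity[ord, ord, drop = FALSE])
}

#' Interphoton propagator matrices of a rate matrix
#'
#' Computes `exp(Q * dt)` for a vector of interphoton intervals through a
#' single eigendecomposition of `Q`, so that thousands of distinct intervals
#' cost one matrix decomposition plus one dense product. Falls back to a
#' scaling-and-squaring matrix exponential per interval if `Q` is close to
#' defective.
#'
#' @param Q Conservative rate matrix.
#' @param dt Vector of time intervals (s).
#' @return A `K x K x length(dt)` array of row-stochastic propagators.
#' @export
ctmc_propagators <- function(Q, dt) {
  Q <- as.matrix(Q)
  K <- nrow(Q)
  n <- length(dt)
  if (K == 1) return(array(1, dim = c(1, 1, n)))
  eg <- eigen(Q)
  V <- eg$vectors
  rc <- rcond_complex(V)
  if (is.finite(rc) && rc > 1e-10) {
    W <- solve(V)
    # P(dt) = sum_m exp(lambda_m dt) * (V[,m] outer W[m,]) : one n x K^2 product
    B <- matrix(0 + 0i, K, K * K)
    for (m in seq_len(K)) B[m, ] <- as.vector(outer(V[, m], W[m, ]))
    expL <- exp(outer(dt, eg$values))          # n x K
    flat <- Re(expL %*% B)                     # n x K^2, row r = vec(P(dt_r))
    flat[flat < 0] <- 0                        # clamp eigen-roundoff
    for (i in seq_len(K)) {                    # renormalize rows, vectorized
      cols <- i + K * (0:(K - 1))
      flat[, cols] <- flat[, cols] / rowSums(flat[, cols, drop = FALSE])
    }
    P <- array(t(flat), dim = c(K, K, n))
  } else {
    P <- array(0, dim = c(K, K, n))
    for (i in seq_len(n)) {
      M <- expm_ss(Q * dt[i])
      M[M < 0] <- 0
      P[, , i] <- M / rowSums(M)
    }
  }
  P
}

rcond_complex <- function(V) {
  s <- svd(V, nu = 0, nv = 0)$d
  if (min(s) == 0) return(0)
  min(s) / max(s)
}

# scaling-and-squaring matrix exponential (Pade-free, Taylor at scaled norm)
expm_ss <- function(A) {
  nrm <- max(abs(A))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 2L)
  As <- A / 2^j
  X <- diag(nrow(A))
  term <- X
  for (k in 1:20) {
    term <- term %*% As / k
    X <- X + term
    if (max(abs(term)) < 1e-18) break
  }
  for (k in seq_len(j)) X <- X %*% X
  X
}
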