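#' Quantitative Neighborhoods of Atoms (P, Q) values
#'
#' For the heavy-atom graph with adjacency matrix C, each atom k carries
#' B_k = IP_k - EA_k and A_k = (IP_k + EA_k)/2 (Mulliken electronegativity
#' scale, eV).  With D_B = diag(B) the coupling matrix is
#'   M = D_B^{-1/2} . expm(-C/2) . D_B^{-1/2}
#' and the per-atom descriptors are P_i = sum_k M_ik and
#' Q_i = sum_k M_ik A_k, so each atom sees every other atom's
#' electronegativity damped by the matrix exponential of the
#' connectivity.  Hydrogens are excluded.
#'
#' @param g A `molgraph`.
#' @param props Element property table from [element_properties()].
#' @return Data frame with columns `atom` (heavy-atom index within the
#'   heavy subgraph), `element`, `P`, `Q`.
#' @export
qna_values <- function(g, props = element_properties()) {
  h <- heavy_graph(g)
  n <- nrow(h$atoms)
  if (n == 0L) stop("no heavy atoms")
  ip <- element_lookup(h$atoms$element, "ip_ev", props)
  ea <- element_lookup(h$atoms$element, "ea_ev", props)
  B <- ip - ea
  A <- (ip + ea) / 2
  C <- matrix(0, n, n)
  if (nrow(h$bonds)) {
    C[cbind(h$bonds$a1, h$bonds$a2)] <- 1
    C[cbind(h$bonds$a2, h$bonds$a1)] <- 1
  }
  E <- as.matrix(Matrix::expm(Matrix::Matrix(-C / 2)))
  s <- 1 / sqrt(B)
  M <- E * tcrossprod(s)          # D^-1/2 E D^-1/2
  data.frame(atom = seq_len(n), element = h$atoms$element,
             P = as.numeric(M %*% rep(1, n)),
             Q = as.numeric(M %*% A))
}

chebyshev_t <- function(x, degree) {
  out <- matrix(0, length(x), degree + 1L)
  out[, 1L] <- 1
  if (degree >= 1L) out[, 2L] <- x
  if (degree >= 2L) {
    for (k in 2L:degree) out[, k + 1L] <- 2 * x * out[, k] - out[, k - 1L]
  }
  out
}

#' Fit the scaling of QNA (P, Q) clouds onto [-1, 1]
#'
#' Records the training-set ranges of P and Q for the affine map used by
#' [qna_features()].  Prediction-time values outside the training range
#' are clipped to +/-1 and counted, so the applicability domain can see
#' them.
#'
#' @param points_list List of data frames from [qna_values()].
#' @return An object of class `qna_scaling`.
#' @export
qna_scaling <- function(points_list) {
  P <- unlist(lapply(points_list, `[[`, "P"))
  Q <- unlist(lapply(points_list, `[[`, "Q"))
  s <- list(p_min = min(P), p_max = max(P), q_min = min(Q), q_max = max(Q))
  s$p_degenerate <- s$p_max - s$p_min < 1e-12
  s$q_degenerate <- s$q_max - s$q_min < 1e-12
  class(s) <- "qna_scaling"
  s
}

scale_clip <- function(x, lo, hi, degenerate) {
  if (degenerate) return(rep(0, length(x)))  # polynomial of a constant
  y <- 2 * (x - lo) / (hi - lo) - 1
  pmin(1, pmax(-1, y))
}

#' Fixed-length Chebyshev featurisation of a QNA point cloud
#'
#' Maps each atom's (P, Q) through the training scaling onto [-1, 1],
#' evaluates all products T_a(p) * T_b(q) for 0 <= a, b <= degree
#' (Chebyshev polynomials of the first kind) and averages over atoms.
#' Feature order is a-major: (a=0,b=0), (a=0,b=1), ..., so degree 1
#' gives (1, q, p, pq) for a single atom.
#'
#' @param points Data frame from [qna_values()].
#' @param scaling A `qna_scaling` fitted on the training set.
#' @param degree Maximum polynomial degree per axis (>= 0, default 2).
#' @return Named numeric vector of length (degree+1)^2; attribute
#'   `n_clipped` counts atoms outside the training P/Q box.
#' @export
qna_features <- function(points, scaling, degree = 2L) {
  if (degree < 0L) stop("degree must be >= 0")
  if (!nrow(points)) stop("empty QNA point set")
  raw_p <- points$P; raw_q <- points$Q
  p <- scale_clip(raw_p, scaling$p_min, scaling$p_max, scaling$p_degenerate)
  q <- scale_clip(raw_q, scaling$q_min, scaling$q_max, scaling$q_degenerate)
  n_clipped <- sum(raw_p < scaling$p_min - 1e-12 | raw_p > scaling$p_max + 1e-12 |
                   raw_q < scaling$q_min - 1e-12 | raw_q > scaling$q_max + 1e-12)
  Tp <- chebyshev_t(p, degree)
  Tq <- chebyshev_t(q, degree)
  feats <- numeric((degree + 1L)^2)
  nms <- character(length(feats))
  k <- 0L
  for (a in 0:degree) {
    for (b in 0:degree) {
      k <- k + 1L
      feats[k] <- mean(Tp[, a + 1L] * Tq[, b + 1L])
      nms[k] <- sprintf("qna_p%d_q%d", a, b)
    }
  }
  names(feats) <- nms
  attr(feats, "n_clipped") <- n_clipped
  feats
}
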