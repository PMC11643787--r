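# Independent oracles used across the suite.  Each reimplements the
# quantity it checks from first principles, by a different route than
# the package code takes.

# dense matrix exponential by scaling-and-squaring of a high-order
# Taylor sum (independent of Matrix::expm)
oracle_expm <- function(A, order = 30L) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 2L)
  B <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% B / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# QNA (P, Q) by the oracle exponential
oracle_qna <- function(g, props = element_properties()) {
  h <- scrqsar:::heavy_graph(g)
  n <- nrow(h$atoms)
  ip <- props[h$atoms$element, "ip_ev"]
  ea <- props[h$atoms$element, "ea_ev"]
  B <- ip - ea; A <- (ip + ea) / 2
  C <- matrix(0, n, n)
  if (nrow(h$bonds)) {
    C[cbind(h$bonds$a1, h$bonds$a2)] <- 1
    C[cbind(h$bonds$a2, h$bonds$a1)] <- 1
  }
  M <- diag(1 / sqrt(B), n) %*% oracle_expm(-C / 2) %*% diag(1 / sqrt(B), n)
  list(P = as.numeric(M %*% rep(1, n)), Q = as.numeric(M %*% A))
}

# cycle membership by edge-deletion connectivity (an edge lies on a
# cycle iff its endpoints stay connected without it); BFS in plain R
oracle_ring_atoms <- function(g) {
  n <- nrow(g$atoms)
  bonds <- g$bonds
  connected_without <- function(skip, from, to) {
    seen <- rep(FALSE, n)
    queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(nrow(bonds))) {
        if (k == skip) next
        nb <- if (bonds$a1[k] == v) bonds$a2[k]
              else if (bonds$a2[k] == v) bonds$a1[k] else next
        if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    seen[to]
  }
  in_ring <- rep(FALSE, n)
  for (k in seq_len(nrow(bonds))) {
    if (connected_without(k, bonds$a1[k], bonds$a2[k])) {
      in_ring[c(bonds$a1[k], bonds$a2[k])] <- TRUE
    }
  }
  in_ring
}

# MNA multiset by an independent recursive implementation
oracle_mna <- function(g, max_level) {
  n <- nrow(g$atoms)
  marks <- ifelse(g$atoms$in_ring, g$atoms$element,
                  paste0("-", g$atoms$element))
  nbrs <- lapply(seq_len(n), function(a) {
    c(g$bonds$a2[g$bonds$a1 == a], g$bonds$a1[g$bonds$a2 == a])
  })
  desc <- function(a, lev) {
    if (lev == 0L) return(marks[a])
    inner <- sort(vapply(nbrs[[a]], desc, "", lev = lev - 1L),
                  method = "radix")
    paste0(marks[a], "(", paste(inner, collapse = ""), ")")
  }
  all <- unlist(lapply(0:max_level, function(lev)
    vapply(seq_len(n), desc, "", lev = lev)))
  tab <- table(all)
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

# external-validation metrics coded directly from the formula
# definitions, with explicit sums
oracle_metrics <- function(obs, pred, train_mean = NULL) {
  n <- length(obs)
  mo <- sum(obs) / n; mp <- sum(pred) / n
  r <- sum((obs - mo) * (pred - mp)) /
    sqrt(sum((obs - mo)^2) * sum((pred - mp)^2))
  r2 <- r^2
  k1 <- sum(obs * pred) / sum(pred^2)
  r0_2 <- 1 - sum((obs - k1 * pred)^2) / sum((obs - mo)^2)
  k2 <- sum(obs * pred) / sum(obs^2)
  r0p_2 <- 1 - sum((pred - k2 * obs)^2) / sum((pred - mp)^2)
  rm2 <- r2 * (1 - sqrt(abs(r2 - r0_2)))
  rm2p <- r2 * (1 - sqrt(abs(r2 - r0p_2)))
  sxy <- sum((obs - mo) * (pred - mp)) / n
  sx2 <- sum((obs - mo)^2) / n
  sy2 <- sum((pred - mp)^2) / n
  ccc <- 2 * sxy / (sx2 + sy2 + (mo - mp)^2)
  err <- pred - obs
  qf1 <- if (is.null(train_mean)) NA_real_ else
    1 - sum(err^2) / sum((obs - train_mean)^2)
  qf2 <- 1 - sum(err^2) / sum((obs - mo)^2)
  mae <- sum(abs(err)) / n
  sd_abs <- sqrt(sum((abs(err) - mae)^2) / n)
  list(r2 = r2, r0_2 = r0_2, r0p_2 = r0p_2, rm2 = rm2, rm2p = rm2p,
       rm2_bar = (rm2 + rm2p) / 2, delta_rm2 = abs(rm2 - rm2p),
       ccc = ccc, qf1_2 = qf1, qf2_2 = qf2,
       rmse = sqrt(sum(err^2) / n), mae = mae, sd_abs = sd_abs,
       b = mae + 3 * sd_abs)
}
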