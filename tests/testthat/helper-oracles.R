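# Independent oracles used across the suite. These deliberately take the
# slow, literal route (explicit enumeration, direct formulas) so they share
# no code with the implementation they check.

# All set partitions of n items as restricted growth strings (rows = one
# partition each, module ids 1..k). Bell(6) = 203, Bell(8) = 4140.
set_partitions <- function(n) {
  acc <- vector("list", 0)
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      acc[[length(acc) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(maxid + 1L)) rec(c(prefix, v), max(maxid, v))
  }
  rec(integer(0), 0L)
  do.call(rbind, acc)
}

# resolution-scaled modularity via the explicit pairwise matrix
# B_eff = a+ * (W+ - g k+ k+'/2m+)/2m+  -  a- * (W- - g k- k-'/2m-)/2m-
# summed over same-module pairs (diagonal included, as in the definition)
oracle_b_eff <- function(W, gamma = 1, variant = "signed") {
  wp <- pmax(W, 0)
  wn <- pmax(-W, 0)
  if (variant == "positive") wn[] <- 0
  if (variant == "plain") {
    wp <- W
    wn[] <- 0
  }
  m2p <- sum(wp)
  m2n <- sum(wn)
  b <- matrix(0, nrow(W), ncol(W))
  if (m2p > 0) {
    kp <- rowSums(wp)
    b <- b + (wp - gamma * outer(kp, kp) / m2p) / m2p
  }
  if (m2n > 0 && variant == "signed") {
    kn <- rowSums(wn)
    an <- m2n / (m2p + m2n)
    b <- b - an * (wn - gamma * outer(kn, kn) / m2n) / m2n
  }
  b
}

oracle_modularity <- function(W, assignment, gamma = 1, variant = "signed") {
  b <- oracle_b_eff(W, gamma, variant)
  sum(b[outer(assignment, assignment, "==")])
}

# exhaustive optimum over every partition (n <= 8)
oracle_best_q <- function(W, gamma = 1, variant = "signed",
                          partitions = set_partitions(nrow(W))) {
  b <- oracle_b_eff(W, gamma, variant)
  best <- -Inf
  for (r in seq_len(nrow(partitions))) {
    a <- partitions[r, ]
    q <- sum(b[outer(a, a, "==")])
    if (q > best) best <- q
  }
  best
}

# brute-force contingency mutual information (nats)
oracle_mi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (x in unique(a)) {
    for (y in unique(b)) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) {
        mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
      }
    }
  }
  mi
}

oracle_entropy <- function(a) {
  p <- as.numeric(table(a)) / length(a)
  -sum(p * log(p))
}

# symmetric weighted graph with planted blocks plus weight noise
planted_graph <- function(n, k = 2, within = 1, between = 0.1, noise = 0.05) {
  blocks <- sort(rep_len(seq_len(k), n))
  w <- ifelse(outer(blocks, blocks, "=="), within, between)
  eps <- matrix(rnorm(n * n, sd = noise), n)
  w <- w + (eps + t(eps)) / 2
  w <- pmax(w, 0)
  diag(w) <- 0
  list(w = w, blocks = blocks)
}
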