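# Independent oracles and fixture builders used across the suite.

# Build a hit table in code.
make_hits <- function(read_id, genome_id, aln_length, n_ident) {
  h <- data.frame(read_id = read_id, genome_id = genome_id,
                  aln_length = as.integer(aln_length),
                  n_ident = as.integer(n_ident), stringsAsFactors = FALSE)
  class(h) <- c("taxmix_hits", "data.frame")
  h
}

# Random small hit instance: n reads, K genomes, each read hits its source
# plus a random subset of others with lower identity.
random_instance <- function(n, K, p = 0.05, m_mean = 60) {
  src <- sample.int(K, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    L <- max(20L, as.integer(round(rnorm(1, m_mean, 8))))
    x <- rbinom(1L, L, 1 - p)
    others <- setdiff(seq_len(K), src[i])
    extra <- others[runif(length(others)) < 0.4]
    g <- c(src[i], extra)
    xs <- c(max(1L, x), pmax(1L, x - rpois(length(extra), 6)))
    data.frame(read_id = sprintf("r%04d", i), genome_id = sprintf("g%02d", g),
               aln_length = L, n_ident = as.integer(xs),
               stringsAsFactors = FALSE)
  })
  make_hits_df <- do.call(rbind, rows)
  class(make_hits_df) <- c("taxmix_hits", "data.frame")
  make_hits_df
}

# Brute-force log-likelihood: plain sum over every stored entry using
# component_weight() in probability space. Independent of the grouped
# log-sum-exp path inside the package.
brute_loglik <- function(M, pi, p) {
  total <- 0
  for (r in seq_along(M$reads)) {
    sel <- M$i == r
    w <- sum(component_weight(M$x[sel], M$m[r], pi[M$j[sel]], p))
    total <- total + log(w)
  }
  total
}

# Exhaustive grid search over the probability simplex x p grid; returns the
# best log-likelihood found. K must be 2 or 3. Dense probability-space
# matrix algebra throughout — no log-sum-exp, no sparsity.
grid_search_loglik <- function(M, pi_step = 0.01, p_grid = seq(0, 0.1, 0.001)) {
  K <- length(M$genomes)
  stopifnot(K %in% c(2L, 3L))
  if (K == 2L) {
    pis <- lapply(seq(pi_step, 1 - pi_step, pi_step), function(a) c(a, 1 - a))
  } else {
    pis <- list()
    for (a in seq(pi_step, 1 - 2 * pi_step, pi_step))
      for (b in seq(pi_step, 1 - a - pi_step, pi_step))
        pis[[length(pis) + 1L]] <- c(a, b, 1 - a - b)
  }
  Pi <- do.call(cbind, pis)                 # K x (number of pi candidates)
  n <- length(M$reads)
  X <- matrix(0, n, K); X[cbind(M$i, M$j)] <- M$x
  present <- matrix(FALSE, n, K); present[cbind(M$i, M$j)] <- TRUE
  Mm <- matrix(M$m, n, K)
  best <- -Inf
  for (p in p_grid) {
    W <- (1 - p)^X * p^(Mm - X)
    W[!present] <- 0                        # truncation rule, applied identically
    S <- W %*% Pi                           # per-read mixture probabilities
    ll <- colSums(log(S))
    if (max(ll) > best) best <- max(ll)
  }
  best
}

# Dense-matrix EM: materialises n x K matrices (x = 0 at absent entries,
# which are truncated to zero weight exactly as the sparse rule does) and
# iterates with whole-matrix operations. Independent code path from the
# package's grouped sparse engine.
dense_em <- function(M, p0 = 0.05, epsilon = 1e-6, max_iter = 1000L) {
  n <- length(M$reads); K <- length(M$genomes)
  X <- matrix(0, n, K); X[cbind(M$i, M$j)] <- M$x
  present <- matrix(FALSE, n, K); present[cbind(M$i, M$j)] <- TRUE
  m <- M$m
  pi <- rep(1 / K, K); p <- p0
  xl <- function(a, b) { out <- a * log(b); out[a == 0] <- 0; out }
  for (it in seq_len(max_iter)) {
    LW <- matrix(log(pi), n, K, byrow = TRUE) + xl(X, 1 - p) + xl(m - X, p)
    LW[!present] <- -Inf
    rmax <- apply(LW, 1L, max)
    W <- exp(LW - rmax)
    W[!present] <- 0
    denom <- rowSums(W)
    Z <- W / denom
    pi_new <- colSums(Z) / n
    num <- sum(Z * (m - X) * present)
    den <- sum(Z * m * present)
    p_new <- num / den
    done <- max(abs(pi_new - pi)) < epsilon && abs(p_new - p) < epsilon
    pi <- pi_new; p <- p_new
    if (done) break
  }
  list(pi = pi, p = p)
}

# Minimal taxonomy fixture: two strains of one species, a second species in
# the same genus, and a third genome in a different family.
toy_taxonomy <- function() {
  build_taxonomy(data.frame(
    taxon_id = c("strainA1", "strainA2", "spA", "spB", "gAB", "famAB",
                 "strainC", "spC", "gC", "famC", "ord1", "cls1", "phy1", "king"),
    parent_id = c("spA", "spA", "gAB", "gAB", "famAB", "ord1",
                  "spC", "gC", "famC", "ord1", "cls1", "phy1", "king", "king"),
    rank = c("no rank", "no rank", "species", "species", "genus", "family",
             "no rank", "species", "genus", "family", "order", "class",
             "phylum", "kingdom"),
    name = c("Strain A1", "Strain A2", "Species A", "Species B", "Genus AB",
             "Family AB", "Strain C", "Species C", "Genus C", "Family C",
             "Order 1", "Class 1", "Phylum 1", "Kingdom 1"),
    stringsAsFactors = FALSE))
}
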