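#' Bootstrap confidence intervals for the genome proportions
#'
#' Resamples reads — rows of the scoring matrix — with replacement, refits
#' the mixture by EM on each resample, and forms percentile intervals for
#' every pi_j. Because the K proportions are inferred simultaneously, each
#' interval is taken at level `1 - alpha/K` (Bonferroni), giving a family
#' confidence level of at least `1 - alpha`. Genomes that drop out of a
#' resample contribute pi_j = 0 to that replicate. The mismatch probability
#' p gets an uncorrected percentile interval. Replicates that hit the
#' iteration cap are kept (discarding them would bias the intervals) and
#' counted in `n_nonconverged`.
#'
#' @param M a [scoring_matrix()].
#' @param B number of bootstrap replicates (the sketch in the source method
#'   suggests B = 1000; smaller values are fine for exploration).
#' @param alpha family-wise error rate (default 0.05 for 95% family level).
#' @param seed RNG seed; identical seeds give identical results.
#' @param p0,epsilon,max_iter EM settings, as in [taxmix()].
#' @return an object of class `taxmix_boot`: `table` (genome, point, lower,
#'   upper), `p` (point, lower, upper), `B`, `alpha`, `seed`,
#'   `n_nonconverged`, and the replicate matrix `pi_boot` (B x K).
#' @export
bootstrap_pi <- function(M, B = 1000L, alpha = 0.05, seed = 1L,
                         p0 = 0.05, epsilon = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(M, "scoring_matrix"))
  if (B < 1L) stop("B must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- length(M$reads); K <- length(M$genomes)
  point <- .em_engine(M$i, M$j, M$x, M$m, n, K, rep(1 / K, K), p0,
                      epsilon, max_iter, reads = M$reads)
  row_entries <- split(seq_along(M$i), M$i)   # entries of each read, in order
  row_len <- lengths(row_entries)
  set.seed(seed)
  pi_boot <- matrix(0, B, K, dimnames = list(NULL, M$genomes))
  p_boot <- numeric(B)
  nonconv <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    e <- unlist(row_entries[idx], use.names = FALSE)
    ib <- rep(seq_len(n), times = row_len[idx])
    jb <- M$j[e]
    present <- sort(unique(jb))
    fit <- .em_engine(ib, match(jb, present), M$x[e], M$m[idx], n,
                      length(present), rep(1 / length(present), length(present)),
                      p0, epsilon, max_iter)
    pi_boot[b, present] <- fit$pi
    p_boot[b] <- fit$p
    if (!fit$converged) nonconv <- nonconv + 1L
  }
  a_bonf <- alpha / K
  lo <- apply(pi_boot, 2L, quantile, probs = a_bonf / 2, names = FALSE)
  hi <- apply(pi_boot, 2L, quantile, probs = 1 - a_bonf / 2, names = FALSE)
  structure(list(
    table = data.frame(genome_id = M$genomes, point = point$pi,
                       lower = lo, upper = hi, stringsAsFactors = FALSE),
    p = c(point = point$p,
          lower = quantile(p_boot, alpha / 2, names = FALSE),
          upper = quantile(p_boot, 1 - alpha / 2, names = FALSE)),
    B = as.integer(B), alpha = alpha, seed = seed,
    n_nonconverged = nonconv, pi_boot = pi_boot),
    class = "taxmix_boot")
}

#' @export
print.taxmix_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: B = %d resamples, family level %.0f%% (Bonferroni over %d proportions)\n",
              x$B, 100 * (1 - x$alpha), nrow(x$table)))
  if (x$n_nonconverged > 0L)
    cat("  replicates stopped at max_iter:", x$n_nonconverged, "\n")
  print(head(x$table[order(-x$table$point), ], 10L), digits = 4, row.names = FALSE)
  cat(sprintf("  p = %.5g [%.5g, %.5g]\n", x$p[["point"]],
              x$p[["lower"]], x$p[["upper"]]))
  invisible(x)
}

#' Serialise a bootstrap result to JSON
#' @param boot a `taxmix_boot`.
#' @param path output JSON path.
#' @export
write_bootstrap <- function(boot, path) {
  stopifnot(inherits(boot, "taxmix_boot"))
  jsonlite::write_json(
    list(genomes = boot$table$genome_id, point = boot$table$point,
         lower = boot$table$lower, upper = boot$table$upper,
         p = as.list(boot$p), B = boot$B, alpha = boot$alpha,
         seed = boot$seed, n_nonconverged = boot$n_nonconverged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
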