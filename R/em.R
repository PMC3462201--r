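#' Unnormalised mixture-component weight of one hit
#'
#' The probability that a read with `x` identical bases out of a maximum
#' alignment length of `m` arose from genome j is
#' `pi_j * (1-p)^x * p^(m-x)`. The product is evaluated in log space so that
#' realistic read lengths do not underflow; a no-hit entry (x = 0) with
#' m = 35 and p = 0.02 already weighs about 3.4e-60, which is why absent
#' entries can be dropped from every sum.
#'
#' @param x identical matches (bp), `0 <= x <= m`. Vectorised.
#' @param m maximum alignment length (bp) of the read.
#' @param pi_j mixture proportion of genome j, in `[0, 1]`.
#' @param p per-base mismatch probability, in `[0, 1]`.
#' @return the non-negative weight(s).
#' @export
#' @examples
#' component_weight(0, 35, 1, 0.02)   # ~3.4e-60
#' component_weight(97, 100, 0.5, 0.02)
component_weight <- function(x, m, pi_j, p) {
  if (any(x < 0 | x > m)) stop("need 0 <= x <= m")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(pi_j < 0 | pi_j > 1)) stop("pi_j must lie in [0, 1]")
  exp(log(pi_j) + xlogy(x, 1 - p) + xlogy(m - x, p))
}

# Log-weights of every stored entry at (pi, p); entries are (i, j, x) with
# per-read maxima m (length n). 0*log(0) = 0 so p = 0 with perfect matches
# and pi_j = 0 behave correctly.
.entry_logw <- function(i, j, x, m, pi, p) {
  log(pi)[j] + xlogy(x, 1 - p) + xlogy(m[i] - x, p)
}

# Grouped E-step over entries sorted by read index i.
# Returns z (per entry), per-read log-normalisers, and the log-likelihood.
.e_step_core <- function(i, j, x, m, n, pi, p, reads = NULL) {
  lw <- .entry_logw(i, j, x, m, pi, p)
  cnt <- tabulate(i, n)
  ord <- order(i, lw)
  gmax <- lw[ord][cumsum(cnt)]           # per-read max log-weight
  if (any(!is.finite(gmax))) {
    bad <- which(!is.finite(gmax))[1L]
    id <- if (is.null(reads)) bad else reads[bad]
    stop("read '", id, "' has zero probability under every candidate genome ",
         "at the current parameters")
  }
  w <- exp(lw - gmax[i])
  denom <- unname(rowsum(w, i, reorder = TRUE)[, 1L])
  list(z = w / denom[i], loglik = sum(log(denom) + gmax))
}

# M-step: pi_j = sum_i z_ij / n; p = sum z*(m_i - x) / sum z*m_i.
.m_step_core <- function(i, j, x, m, z, n, K) {
  colz <- numeric(K)
  cs <- rowsum(z, j, reorder = TRUE)
  colz[as.integer(rownames(cs))] <- cs[, 1L]
  me <- m[i]
  list(pi = colz / n, p = sum(z * (me - x)) / sum(z * me))
}

# Plain EM engine over triplet data; shared by taxmix() and bootstrap_pi().
.em_engine <- function(i, j, x, m, n, K, pi0, p0, epsilon, max_iter,
                       reads = NULL) {
  pi <- pi0; p <- p0
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- .e_step_core(i, j, x, m, n, pi, p, reads)
    trace[iter] <- es$loglik
    ms <- .m_step_core(i, j, x, m, es$z, n, K)
    done <- max(abs(ms$pi - pi)) < epsilon && abs(ms$p - p) < epsilon
    pi <- ms$pi; p <- ms$p
    if (done) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  final <- .e_step_core(i, j, x, m, n, pi, p, reads)
  trace[iter + 1L] <- final$loglik
  list(pi = pi, p = p, z = final$z, loglik = final$loglik,
       trace = trace, n_iter = iter, converged = converged)
}

#' Fit the genome mixture model by EM
#'
#' Estimates the proportion of reads generated by each candidate genome
#' (`pi`) and the per-base mismatch probability (`p`) by maximising the
#' sparse mixture likelihood: each read i contributes
#' `log sum_j pi_j (1-p)^x_ij p^(m_i - x_ij)` over its stored hits, absent
#' entries being truncated to zero weight. EM alternates computing posterior
#' responsibilities (E-step) with the closed-form updates
#' `pi_j = sum_i z_ij / n` and `p = sum_ij z_ij (m_i - x_ij) / sum_ij z_ij m_i`
#' (M-step) until every parameter moves less than `epsilon` between
#' iterations.
#'
#' @param M a [scoring_matrix()].
#' @param p0 starting mismatch probability (default 0.05; any start in
#'   (0, 0.5) reaches the same optimum on well-posed data).
#' @param pi0 starting proportions; default uniform `1/K`.
#' @param epsilon convergence tolerance on the absolute change of every
#'   parameter (default 1e-6).
#' @param max_iter iteration cap (default 1000). Reaching it returns an
#'   unconverged fit with a warning, not an error.
#' @return an object of class `taxmix`: `pi` (named by genome), `p`,
#'   sparse responsibilities `z` (parallel to the matrix entries),
#'   `loglik`, `trace` (per-iteration log-likelihood, non-decreasing),
#'   `n_iter`, `converged`, and the input matrix `M`.
#' @seealso [assign_reads()], [relative_abundance()], [bootstrap_pi()]
#' @export
taxmix <- function(M, p0 = 0.05, pi0 = NULL, epsilon = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(M, "scoring_matrix"))
  if (!(epsilon > 0)) stop("epsilon must be positive")
  if (max_iter < 1L) stop("max_iter must be at least 1")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  n <- length(M$reads); K <- length(M$genomes)
  if (is.null(pi0)) pi0 <- rep(1 / K, K)
  if (length(pi0) != K || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-8)
    stop("pi0 must be ", K, " non-negative proportions summing to 1")
  fit <- .em_engine(M$i, M$j, M$x, M$m, n, K, pi0, p0, epsilon, max_iter,
                    reads = M$reads)
  if (!fit$converged)
    warning("EM stopped at max_iter = ", max_iter, " without converging")
  structure(list(pi = setNames(fit$pi, M$genomes), p = fit$p,
                 z = fit$z, loglik = fit$loglik, trace = fit$trace,
                 n_iter = fit$n_iter, converged = fit$converged,
                 epsilon = epsilon, M = M),
            class = "taxmix")
}

#' @export
print.taxmix <- function(x, ...) {
  n <- length(x$M$reads); K <- length(x$M$genomes)
  cat("Genome mixture model fitted by EM\n")
  cat(sprintf("  %d reads, %d candidate genomes; log-likelihood %.4f\n",
              n, K, x$loglik))
  cat(sprintf("  mismatch probability p = %.6g\n", x$p))
  cat(sprintf("  %d iterations (%s)\n", x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  top <- sort(x$pi, decreasing = TRUE)
  top <- head(top, 5L)
  cat("  largest proportions:\n")
  for (g in names(top)) cat(sprintf("    %-20s %.5f\n", g, top[[g]]))
  invisible(x)
}

#' @export
coef.taxmix <- function(object, ...) {
  c(setNames(object$pi, paste0("pi.", names(object$pi))), p = object$p)
}

#' @export
logLik.taxmix <- function(object, ...) {
  structure(object$loglik, df = length(object$pi), # K-1 proportions + p
            nobs = length(object$M$reads), class = "logLik")
}

#' @export
summary.taxmix <- function(object, ...) {
  n <- length(object$M$reads)
  thresh <- 1 / (10 * n)  # reporting threshold: below this a genome is called absent
  tab <- data.frame(genome = names(object$pi), pi = unname(object$pi),
                    detected = unname(object$pi) >= thresh,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$pi), ]
  rownames(tab) <- NULL
  structure(list(table = tab, p = object$p, loglik = object$loglik,
                 n = n, K = length(object$pi), n_iter = object$n_iter,
                 converged = object$converged, threshold = thresh),
            class = "summary.taxmix")
}

#' @export
print.summary.taxmix <- function(x, ...) {
  cat(sprintf("Genome mixture fit: n = %d reads, K = %d candidate genomes\n",
              x$n, x$K))
  cat(sprintf("p (per-base mismatch) = %.6g; log-likelihood = %.4f\n",
              x$p, x$loglik))
  cat(sprintf("%d of %d genomes detected (pi >= 1/(10n) = %.3g)\n",
              sum(x$table$detected), x$K, x$threshold))
  print(head(x$table, 20L), digits = 4)
  if (nrow(x$table) > 20L) cat("... (", nrow(x$table) - 20L, " more)\n")
  invisible(x)
}

#' @export
fitted.taxmix <- function(object, ...) {
  data.frame(read_id = object$M$reads[object$M$i],
             genome_id = object$M$genomes[object$M$j],
             z = object$z, stringsAsFactors = FALSE)
}

#' Posterior read-to-genome probabilities
#'
#' With `type = "responsibility"` returns the sparse posterior table
#' (read, genome, z); with `type = "assignment"` returns the
#' maximum-posterior assignment of every read (see [assign_reads()]).
#'
#' @param object a fitted `taxmix` model.
#' @param newdata optionally a new [scoring_matrix()] over the same genomes;
#'   default is the training matrix.
#' @param type `"responsibility"` or `"assignment"`.
#' @param ... unused.
#' @export
predict.taxmix <- function(object, newdata = NULL,
                           type = c("responsibility", "assignment"), ...) {
  type <- match.arg(type)
  M <- if (is.null(newdata)) object$M else newdata
  stopifnot(inherits(M, "scoring_matrix"))
  pi <- object$pi[M$genomes]
  if (anyNA(pi))
    stop("newdata contains genomes absent from the fitted model")
  es <- .e_step_core(M$i, M$j, M$x, M$m, length(M$reads), unname(pi),
                     object$p, reads = M$reads)
  if (type == "responsibility")
    return(data.frame(read_id = M$reads[M$i], genome_id = M$genomes[M$j],
                      z = es$z, stringsAsFactors = FALSE))
  .assign_from_z(M, es$z, unname(pi))
}

#' @export
plot.taxmix <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
       xlab = "EM iteration", ylab = "log-likelihood",
       main = "EM log-likelihood ascent", ...)
  invisible(x)
}

#' Simulate hit profiles from a fitted mixture
#'
#' Draws `nsim` replicate hit tables from the fitted model: each read's
#' source genome is drawn from `pi`, its alignment length is resampled from
#' the fitted reads' maximum alignment lengths, and its identical-match
#' count is Binomial(L, 1-p). Cross-genome homology is not resimulated; each
#' simulated read carries a single hit.
#'
#' @param object a fitted `taxmix` model.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `nsim` hit tables (as from [read_hits()]).
#' @export
simulate.taxmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$M$reads)
  K <- length(object$pi)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    src <- sample.int(K, n, replace = TRUE, prob = object$pi)
    L <- sample(object$M$m, n, replace = TRUE)
    x <- rbinom(n, L, 1 - object$p)
    hits <- data.frame(read_id = sprintf("sim%d_r%06d", s, seq_len(n)),
                       genome_id = names(object$pi)[src],
                       aln_length = as.integer(L), n_ident = as.integer(x),
                       stringsAsFactors = FALSE)
    class(hits) <- c("taxmix_hits", "data.frame")
    out[[s]] <- hits
  }
  if (nsim == 1L) out[[1L]] else out
}

#' Log-likelihood of a scoring matrix at given parameters
#'
#' Evaluates `sum_i log sum_j pi_j (1-p)^x_ij p^(m_i - x_ij)` over stored
#' entries (absent entries truncated to zero weight), in log space.
#'
#' @param M a [scoring_matrix()].
#' @param pi genome proportions (length K, summing to 1).
#' @param p per-base mismatch probability.
#' @return the log-likelihood (scalar).
#' @export
mixture_loglik <- function(M, pi, p) {
  stopifnot(inherits(M, "scoring_matrix"))
  if (length(pi) != length(M$genomes))
    stop("pi must have one entry per candidate genome")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must be proportions summing to 1")
  .e_step_core(M$i, M$j, M$x, M$m, length(M$reads), unname(pi), p,
               reads = M$reads)$loglik
}

#' Serialise a fitted mixture to JSON
#'
#' Writes genome order, proportions, mismatch probability, iteration count,
#' convergence flag and final log-likelihood. Responsibilities can be dumped
#' alongside in the sparse TSV dialect of [write_scoring_matrix()].
#'
#' @param fit a fitted `taxmix` model.
#' @param path output JSON path.
#' @param responsibilities optional TSV path for the sparse posterior table.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, responsibilities = NULL) {
  stopifnot(inherits(fit, "taxmix"))
  jsonlite::write_json(
    list(genomes = names(fit$pi), pi = unname(fit$pi), p = fit$p,
         n_iter = fit$n_iter, converged = fit$converged,
         loglik = fit$loglik),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(responsibilities))
    write.table(fitted(fit), responsibilities, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
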