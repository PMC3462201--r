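# Shared by assign_reads() and predict.taxmix(): argmax of the sparse
# posterior rows with deterministic tie-breaking (larger pi, then smaller
# genome index).
.assign_from_z <- function(M, z, pi) {
  n <- length(M$reads)
  # rank entries so that per read the best one sorts last:
  # primary z, tie-break pi of the genome, final tie smaller index j first
  ord <- order(M$i, z, pi[M$j], -M$j)
  cnt <- tabulate(M$i, n)
  top <- ord[cumsum(cnt)]
  # runner-up posterior (NA for single-hit reads)
  runner <- rep(NA_real_, n)
  multi <- cnt > 1L
  if (any(multi)) runner[multi] <- z[ord[cumsum(cnt)[multi] - 1L]]
  assigned <- M$genomes[M$j[top]]
  tab <- data.frame(read_id = M$reads, genome_id = assigned,
                    posterior = z[top], runner_up = runner,
                    stringsAsFactors = FALSE)
  counts <- table(factor(assigned, levels = M$genomes))
  structure(list(assignments = tab,
                 counts = setNames(as.integer(counts), M$genomes),
                 n = n, total_reads = M$total_reads),
            class = "taxmix_assignment")
}

#' Assign each read to its maximum-posterior genome
#'
#' Every read in the scoring matrix is placed in the genome maximising its
#' posterior probability z_ij (a hard 0/1 assignment matrix). Posterior ties
#' go to the genome with the larger estimated proportion, then to the
#' smaller genome index, so assignment is deterministic. Per-genome read
#' counts are the column sums of the induced assignment matrix. Reads with
#' no hits never enter the matrix and are reported separately through
#' `total_reads`.
#'
#' @param fit a fitted [taxmix()] model. An unconverged fit aborts unless
#'   `accept_unconverged = TRUE`.
#' @param accept_unconverged set `TRUE` to assign from an unconverged fit.
#' @return an object of class `taxmix_assignment`: `assignments` (read_id,
#'   genome_id, posterior, runner_up), `counts` (per-genome read tally),
#'   `n` matrix reads, `total_reads` including no-hit reads.
#' @export
assign_reads <- function(fit, accept_unconverged = FALSE) {
  stopifnot(inherits(fit, "taxmix"))
  if (!fit$converged && !accept_unconverged)
    stop("fit did not converge; pass accept_unconverged = TRUE to assign anyway")
  .assign_from_z(fit$M, fit$z, unname(fit$pi))
}

#' @export
print.taxmix_assignment <- function(x, ...) {
  cat("Read assignments:", x$n, "reads across",
      sum(x$counts > 0L), "genomes\n")
  if (x$total_reads > x$n)
    cat("Plus", x$total_reads - x$n, "no-hit reads left unassigned\n")
  top <- sort(x$counts, decreasing = TRUE)
  top <- head(top[top > 0L], 10L)
  for (g in names(top)) cat(sprintf("  %-20s %d\n", g, top[[g]]))
  invisible(x)
}

#' Write assignments as TSV
#' @param assignment a `taxmix_assignment`.
#' @param path output path.
#' @export
write_assignments <- function(assignment, path) {
  stopifnot(inherits(assignment, "taxmix_assignment"))
  write.table(assignment$assignments[c("read_id", "genome_id", "posterior")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score assignments against a truth table at each taxonomic rank
#'
#' A read is correct at a rank when its assigned genome's ancestor at that
#' rank equals its true genome's ancestor at that rank (so a read assigned
#' to the wrong strain of the right species is still correct at Species and
#' above). TP and FP are percentages of `total_reads` — all sequenced reads
#' including those without hits — so TP + FP < 100 whenever some reads went
#' unassigned. Reads whose *true* genome has no ancestor at a rank are
#' excluded from that rank's tally (counted in `n_excluded`); reads whose
#' assigned genome lacks the rank are counted as unassigned there (neither
#' TP nor FP).
#'
#' @param assignment a `taxmix_assignment` from [assign_reads()].
#' @param truth named character vector or two-column data.frame mapping
#'   read_id to the true source genome/taxon id.
#' @param taxonomy a [read_taxonomy()] tree resolving all genomes.
#' @param total_reads total sequenced reads (>= assigned reads); defaults to
#'   the assignment's `total_reads`.
#' @param ranks ranks to evaluate, lowest first.
#' @return a data.frame of class `taxmix_eval`: rank, TP, FP (percent, 2
#'   decimals), n_correct, n_incorrect, n_excluded, n_total.
#' @export
evaluate_assignments <- function(assignment, truth, taxonomy,
                                 total_reads = NULL,
                                 ranks = c("species", "genus", "family",
                                           "order", "class", "phylum",
                                           "kingdom")) {
  stopifnot(inherits(assignment, "taxmix_assignment"))
  if (is.data.frame(truth)) truth <- setNames(as.character(truth[[2L]]),
                                              as.character(truth[[1L]]))
  if (is.null(total_reads)) total_reads <- assignment$total_reads
  tab <- assignment$assignments
  if (total_reads < nrow(tab))
    stop("total_reads is smaller than the number of assigned reads")
  tr <- truth[tab$read_id]
  if (anyNA(tr))
    stop("truth table is missing ", sum(is.na(tr)), " assigned read(s)")
  taxa <- unique(c(tab$genome_id, tr))
  unknown <- setdiff(taxa, names(taxonomy$parent))
  if (length(unknown))
    stop("taxa not in the taxonomy: ", paste(head(unknown, 5L), collapse = ", "))
  out <- vector("list", length(ranks))
  for (k in seq_along(ranks)) {
    anc <- ancestor_at_rank(taxonomy, taxa, ranks[k])
    a_anc <- anc[match(tab$genome_id, taxa)]
    t_anc <- anc[match(tr, taxa)]
    eligible <- !is.na(t_anc)            # true lineage must reach this rank
    correct <- eligible & !is.na(a_anc) & a_anc == t_anc
    incorrect <- eligible & !is.na(a_anc) & a_anc != t_anc
    out[[k]] <- data.frame(
      rank = ranks[k],
      TP = round(sum(correct) / total_reads * 100, 2),
      FP = round(sum(incorrect) / total_reads * 100, 2),
      n_correct = sum(correct), n_incorrect = sum(incorrect),
      n_excluded = sum(!eligible), n_total = as.integer(total_reads),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("taxmix_eval", "data.frame")
  res
}
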