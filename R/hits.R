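#' Describe the columns of a tabular hit file
#'
#' Homology-search programs emit tabular output whose columns vary by
#' invocation. A dialect names the 1-based columns holding the read id, the
#' subject taxon/genome id, the alignment length, and the identical-match
#' count. The default matches 13-column tabular output: the standard 12
#' columns (qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore) with the identical-match count (nident) appended as
#' column 13, since the stock 12-column format reports percent identity but
#' not the raw match count the model needs.
#'
#' If `n_ident` is `NA` the identical-match count is derived from percent
#' identity as `round(pident * aln_length / 100)`.
#'
#' @param read_id column holding the read (query) identifier.
#' @param genome_id column holding the subject taxon or genome identifier.
#' @param aln_length column holding the alignment length in bp.
#' @param n_ident column holding the identical-match count in bp, or `NA` to
#'   derive it from `pident`.
#' @param pident column holding percent identity; only consulted when
#'   `n_ident` is `NA`.
#' @return an object of class `hit_dialect`.
#' @export
#' @examples
#' hit_dialect()                      # 12 standard columns + nident
#' hit_dialect(n_ident = NA)          # derive matches from percent identity
hit_dialect <- function(read_id = 1L, genome_id = 2L, aln_length = 4L,
                        n_ident = 13L, pident = 3L) {
  d <- list(read_id = as.integer(read_id), genome_id = as.integer(genome_id),
            aln_length = as.integer(aln_length), n_ident = as.integer(n_ident),
            pident = as.integer(pident))
  for (f in c("read_id", "genome_id", "aln_length")) {
    if (is.na(d[[f]]) || d[[f]] < 1L)
      stop("dialect column '", f, "' must be a positive column index")
  }
  if (is.na(d$n_ident) && (is.na(d$pident) || d$pident < 1L))
    stop("dialect needs either an 'n_ident' column or a 'pident' column")
  class(d) <- "hit_dialect"
  d
}

#' Read alignment hits from a tabular file
#'
#' Parses a tab-separated hit file (gzip transparent) into a hit table with
#' one row per alignment: `read_id`, `genome_id`, `aln_length` (bp) and
#' `n_ident` (identical matches, bp). Rows violating the hit invariants
#' (`0 <= n_ident <= aln_length`, positive alignment length, non-empty ids)
#' abort with the offending line number.
#'
#' @param path path to a tab-separated hit file (may be gzipped).
#' @param dialect a [hit_dialect()] mapping columns to fields.
#' @return a `data.frame` of class `taxmix_hits` with columns `read_id`,
#'   `genome_id`, `aln_length`, `n_ident`.
#' @export
read_hits <- function(path, dialect = hit_dialect()) {
  if (!inherits(dialect, "hit_dialect")) stop("'dialect' must be a hit_dialect")
  if (!file.exists(path)) stop("hit file not found: ", path)
  raw <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", colClasses = "character",
                    stringsAsFactors = FALSE, fill = TRUE)
  if (nrow(raw) == 0L) stop("hit file is empty: ", path)
  need <- c(dialect$read_id, dialect$genome_id, dialect$aln_length,
            if (is.na(dialect$n_ident)) dialect$pident else dialect$n_ident)
  if (max(need) > ncol(raw))
    stop("hit file has ", ncol(raw), " columns but the dialect requires column ",
         max(need))
  len <- suppressWarnings(as.numeric(raw[[dialect$aln_length]]))
  if (is.na(dialect$n_ident)) {
    pid <- suppressWarnings(as.numeric(raw[[dialect$pident]]))
    ident <- round(pid * len / 100)
  } else {
    ident <- suppressWarnings(as.numeric(raw[[dialect$n_ident]]))
  }
  rid <- raw[[dialect$read_id]]
  gid <- raw[[dialect$genome_id]]
  bad <- is.na(len) | is.na(ident) | len <= 0 | ident < 0 | ident > len |
    len != floor(len) | ident != floor(ident) |
    !nzchar(rid) | !nzchar(gid)
  if (any(bad))
    stop("malformed hit at line ", which(bad)[1L], " of ", path,
         " (need non-empty ids and 0 <= n_ident <= aln_length)")
  hits <- data.frame(read_id = rid, genome_id = gid,
                     aln_length = as.integer(len), n_ident = as.integer(ident),
                     stringsAsFactors = FALSE)
  class(hits) <- c("taxmix_hits", "data.frame")
  hits
}

#' Keep one hit per read and genome
#'
#' A read may align to several loci of the same genome; only the hit with the
#' largest identical-match count represents that genome. Ties on the match
#' count keep the longer alignment; remaining ties keep the hit encountered
#' first. Row order of the survivors follows the input. Idempotent.
#'
#' @param hits a hit table as returned by [read_hits()].
#' @return the collapsed hit table, at most one row per (read, genome).
#' @export
collapse_hits <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("read_id", "genome_id", "aln_length", "n_ident") %in% names(hits)))
  if (nrow(hits) <= 1L) return(hits)
  key <- paste(hits$read_id, hits$genome_id, sep = "\r")
  ord <- order(key, -hits$n_ident, -hits$aln_length)  # stable: first wins ties
  sel <- sort(ord[!duplicated(key[ord])])
  out <- hits[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the sparse read-by-genome scoring matrix
#'
#' Rows are reads, columns candidate genomes; the stored entry (i, j) is the
#' pair (x_ij, L_ij) = (identical matches, alignment length) of read i's best
#' hit in genome j. Absent entries mean "no hit" (x = 0). Reads and genomes
#' are indexed in first-appearance order of the collapsed hit stream. Each
#' read carries m_i, its maximum alignment length over stored hits, which is
#' the exponent base of the mismatch term (1-p)^x * p^(m_i - x). Hits with
#' zero identical matches carry no signal and are treated as absent.
#'
#' @param hits a hit table ([read_hits()] output); collapsed internally.
#' @param total_reads optional total number of sequenced reads including
#'   those with no hits; used to report the unassigned denominator.
#' @return an object of class `scoring_matrix`: read/genome id vectors,
#'   parallel entry vectors `i`, `j`, `x`, `L` sorted by read index, per-read
#'   maxima `m`, and `total_reads`.
#' @export
scoring_matrix <- function(hits, total_reads = NULL) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) stop("cannot build a scoring matrix from zero hits")
  hits <- collapse_hits(hits)
  hits <- hits[hits$n_ident > 0L, , drop = FALSE]
  if (nrow(hits) == 0L) stop("no hits with a positive identical-match count")
  reads <- unique(hits$read_id)
  genomes <- unique(hits$genome_id)
  i <- match(hits$read_id, reads)
  j <- match(hits$genome_id, genomes)
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  x <- hits$n_ident[ord]; L <- hits$aln_length[ord]
  m <- vapply(split(L, i), max, integer(1L))
  names(m) <- NULL
  if (is.null(total_reads)) total_reads <- length(reads)
  if (total_reads < length(reads))
    stop("total_reads (", total_reads, ") is smaller than the number of reads with hits (",
         length(reads), ")")
  structure(list(reads = reads, genomes = genomes,
                 i = i, j = j, x = x, L = L, m = m,
                 total_reads = as.integer(total_reads)),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  n <- length(x$reads); K <- length(x$genomes)
  cat("Sparse scoring matrix:", n, "reads x", K, "genomes,",
      length(x$x), "stored hits",
      sprintf("(density %.4f)\n", length(x$x) / (n * K)))
  if (x$total_reads > n)
    cat("Unassigned (no-hit) reads:", x$total_reads - n, "of", x$total_reads, "total\n")
  invisible(x)
}

#' @export
dim.scoring_matrix <- function(x) c(length(x$reads), length(x$genomes))

#' Materialise a scoring matrix as dense matrices
#'
#' Returns dense n x K matrices of identical matches and alignment lengths
#' with 0 at absent entries; mainly for inspection and small examples.
#'
#' @param x a `scoring_matrix`.
#' @param ... unused.
#' @export
as.matrix.scoring_matrix <- function(x, ...) {
  n <- length(x$reads); K <- length(x$genomes)
  X <- matrix(0L, n, K, dimnames = list(x$reads, x$genomes))
  X[cbind(x$i, x$j)] <- x$x
  X
}

#' Write / read a scoring matrix in its sparse on-disk format
#'
#' The matrix is written as a TSV of stored entries (read_id, genome_id, x, L)
#' plus a JSON sidecar (`<path>.json`) recording read order, genome order,
#' per-read maximum alignment lengths and the total read count, so the
#' round-trip reproduces indexing exactly.
#'
#' @param M a `scoring_matrix`.
#' @param path output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `write_scoring_matrix` returns `path` invisibly;
#'   `read_scoring_matrix` returns the reconstructed `scoring_matrix`.
#' @export
write_scoring_matrix <- function(M, path) {
  stopifnot(inherits(M, "scoring_matrix"))
  df <- data.frame(read_id = M$reads[M$i], genome_id = M$genomes[M$j],
                   x = M$x, L = M$L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(reads = M$reads, genomes = M$genomes,
                            m = M$m, total_reads = M$total_reads),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_scoring_matrix
#' @export
read_scoring_matrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer", "integer"))
  i <- match(df$read_id, side$reads)
  j <- match(df$genome_id, side$genomes)
  if (anyNA(i) || anyNA(j))
    stop("scoring matrix TSV and its JSON sidecar disagree on read/genome ids")
  ord <- order(i, j)
  structure(list(reads = as.character(side$reads),
                 genomes = as.character(side$genomes),
                 i = i[ord], j = j[ord], x = df$x[ord], L = df$L[ord],
                 m = as.integer(side$m),
                 total_reads = as.integer(side$total_reads)),
            class = "scoring_matrix")
}
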