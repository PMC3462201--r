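#' Relative genome abundance (copy number) from read proportions
#'
#' The number of reads a genome generates is proportional to its copy number
#' times its length, so under uniform read sampling the relative copy number
#' of genome j is `a_j = (pi_j / l_j) / sum_k (pi_k / l_k)`. Genomes without
#' a known length are dropped with a warning and the remainder renormalised.
#'
#' @param pi named vector of read proportions (a fitted `taxmix` model or
#'   its `pi`), summing to 1.
#' @param lengths named vector of genome lengths in bp (strictly positive),
#'   or a two-column data.frame (taxon_id, length) such as
#'   [read_genome_lengths()] returns.
#' @return a data.frame of class `taxmix_abundance`: genome_id, length,
#'   read_proportion, relative_abundance (summing to 1).
#' @export
#' @examples
#' relative_abundance(c(a = 0.5, b = 0.5), c(a = 1e6, b = 2e6))
#' # genome a is half the length, so it carries twice the copies: 2/3 vs 1/3
relative_abundance <- function(pi, lengths) {
  if (inherits(pi, "taxmix")) pi <- pi$pi
  if (is.data.frame(lengths))
    lengths <- setNames(as.numeric(lengths[[2L]]), as.character(lengths[[1L]]))
  if (is.null(names(pi)) && is.null(names(lengths))) {
    if (length(lengths) < length(pi))
      stop("lengths vector is shorter than pi")
    names(pi) <- names(lengths) <- paste0("g", seq_along(pi))
  }
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1")
  known <- names(pi)[names(pi) %in% names(lengths) & !is.na(lengths[names(pi)])]
  if (length(known) == 0L) stop("no genome in pi has a known length")
  if (length(known) < length(pi)) {
    warning(length(pi) - length(known),
            " genome(s) lack a length and were dropped; proportions renormalised")
    pi <- pi[known] / sum(pi[known])
  }
  l <- as.numeric(lengths[names(pi)])
  if (any(l <= 0)) stop("genome lengths must be strictly positive")
  dens <- pi / l
  out <- data.frame(genome_id = names(pi), length = l,
                    read_proportion = unname(pi),
                    relative_abundance = unname(dens / sum(dens)),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxmix_abundance", "data.frame")
  out
}

#' Read a genome-length table
#'
#' Two-column TSV with header: taxon_id, length (bp).
#'
#' @param path TSV path.
#' @return data.frame with columns taxon_id, length.
#' @export
read_genome_lengths <- function(path) {
  if (!file.exists(path)) stop("genome-length file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   colClasses = c("character", "numeric"))
  names(df)[1:2] <- c("taxon_id", "length")
  if (any(!is.finite(df$length) | df$length <= 0))
    stop("genome lengths must be positive numbers")
  df
}
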