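#' Configure a synthetic metagenomic community
#'
#' Describes the community a synthetic hit profile is drawn from: K genomes
#' with proportions `pi`, a pooled per-base mismatch probability `p`, read
#' lengths around `read_length_mean`, and a simple homology model under
#' which a read may also hit non-source genomes ("cross-hits") with reduced
#' identity. The cross-hit model is a synthetic stand-in for real
#' between-genome sequence similarity: per read the number of non-source
#' genomes hit is Binomial(K-1, `cross_hit_prob`), the genomes are drawn
#' uniformly, and each cross-hit loses Poisson(`cross_hit_penalty`) identical
#' matches relative to the source hit (dropped when fewer than one remains).
#' A read is a no-hit read (present in the truth table, absent from the hit
#' file) with probability `no_hit_prob`.
#'
#' @param genomes number of genomes K, or a character vector of genome ids.
#' @param pi true proportions (default equal); must sum to 1.
#' @param p true per-base mismatch probability.
#' @param n_reads number of reads to simulate.
#' @param read_length_mean,read_length_sd alignment-length law, bp; lengths
#'   are rounded Gaussians floored at 35 bp.
#' @param cross_hit_prob per-(read, non-source-genome) probability of a
#'   homology-induced secondary hit.
#' @param cross_hit_penalty expected extra mismatches of a cross-hit.
#' @param no_hit_prob probability a read has no hit at all.
#' @param genome_lengths genome lengths in bp (default spread over 2-6 Mb).
#' @param genus_size,family_size how many consecutive species share a genus,
#'   and genera a family, in the generated synthetic lineage; higher ranks
#'   keep doubling the group size.
#' @param seed RNG seed.
#' @return an object of class `community_config`.
#' @export
community_config <- function(genomes, pi = NULL, p = 0.027,
                             n_reads = 150000L,
                             read_length_mean = 100, read_length_sd = 10,
                             cross_hit_prob = 0.05, cross_hit_penalty = 5,
                             no_hit_prob = 0.02, genome_lengths = NULL,
                             genus_size = 2L, family_size = 2L,
                             seed = 1L) {
  if (is.numeric(genomes) && length(genomes) == 1L)
    genomes <- sprintf("g%03d", seq_len(genomes))
  K <- length(genomes)
  if (is.null(pi)) pi <- rep(1 / K, K)
  if (length(pi) != K || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be ", K, " non-negative proportions summing to 1")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (cross_hit_prob < 0 || cross_hit_prob > 1 ||
      no_hit_prob < 0 || no_hit_prob > 1)
    stop("probabilities must lie in [0, 1]")
  if (is.null(genome_lengths))
    genome_lengths <- round(seq(2e6, 6e6, length.out = K))
  if (length(genome_lengths) != K || any(genome_lengths <= 0))
    stop("genome_lengths must be ", K, " positive values")
  structure(list(genomes = as.character(genomes), pi = pi, p = p,
                 n_reads = as.integer(n_reads),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 cross_hit_prob = cross_hit_prob,
                 cross_hit_penalty = cross_hit_penalty,
                 no_hit_prob = no_hit_prob,
                 genome_lengths = setNames(as.numeric(genome_lengths), genomes),
                 genus_size = as.integer(genus_size),
                 family_size = as.integer(family_size),
                 seed = as.integer(seed)),
            class = "community_config")
}

#' @export
print.community_config <- function(x, ...) {
  cat(sprintf("Synthetic community: K = %d genomes, %d reads, p = %.4g\n",
              length(x$genomes), x$n_reads, x$p))
  cat(sprintf("  read length ~ N(%g, %g^2), cross-hit prob %.3g (penalty %.3g), no-hit prob %.3g, seed %d\n",
              x$read_length_mean, x$read_length_sd, x$cross_hit_prob,
              x$cross_hit_penalty, x$no_hit_prob, x$seed))
  invisible(x)
}

# Synthetic lineage: each genome is an unranked strain under its own
# species; species are grouped into genera, genera into families, and each
# higher rank merges pairs, ending at a single kingdom root.
.synthetic_lineage <- function(genomes, genus_size = 2L, family_size = 2L) {
  K <- length(genomes)
  lvl <- function(idx, prefix) paste0(prefix, sprintf("%03d", idx))
  sp <- seq_len(K)
  ge <- ceiling(sp / genus_size)
  fa <- ceiling(ge / family_size)
  or <- ceiling(fa / 2L)
  cl <- ceiling(or / 2L)
  ph <- ceiling(cl / 2L)
  rows <- list(
    data.frame(taxon_id = genomes, parent_id = lvl(sp, "sp"),
               rank = "no rank", name = paste0(genomes, " strain"),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = lvl(unique(sp), "sp"),
               parent_id = lvl(ge[!duplicated(sp)], "ge"),
               rank = "species", name = lvl(unique(sp), "Species "),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = lvl(unique(ge), "ge"),
               parent_id = lvl(fa[!duplicated(ge)], "fa"),
               rank = "genus", name = lvl(unique(ge), "Genus "),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = lvl(unique(fa), "fa"),
               parent_id = lvl(or[!duplicated(fa)], "or"),
               rank = "family", name = lvl(unique(fa), "Family "),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = lvl(unique(or), "or"),
               parent_id = lvl(cl[!duplicated(or)], "cl"),
               rank = "order", name = lvl(unique(or), "Order "),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = lvl(unique(cl), "cl"),
               parent_id = lvl(ph[!duplicated(cl)], "ph"),
               rank = "class", name = lvl(unique(cl), "Class "),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = lvl(unique(ph), "ph"), parent_id = "king001",
               rank = "phylum", name = lvl(unique(ph), "Phylum "),
               stringsAsFactors = FALSE),
    data.frame(taxon_id = "king001", parent_id = "king001",
               rank = "kingdom", name = "Kingdom synthetica",
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Simulate a hit profile, truth table, taxonomy and genome lengths
#'
#' Draws each read's source genome from `pi`, its alignment length from the
#' configured read-length law, and its identical-match count as
#' Binomial(L, 1-p) — exactly the generative structure the mixture model
#' assumes — then adds homology cross-hits and no-hit reads as configured
#' (see [community_config()]). The outputs round-trip through [read_hits()]
#' and [scoring_matrix()].
#'
#' @param config a [community_config()].
#' @param dir optional directory; when given, writes `hits.tsv` (13-column
#'   tabular, identical-match count in column 13), `taxonomy.tsv`,
#'   `genome_lengths.tsv` and `truth.tsv` there.
#' @return an object of class `taxmix_sim`: `hits` (hit table),
#'   `truth` (read_id, genome_id for every read incl. no-hit reads),
#'   `taxonomy` (node table), `lengths` (taxon_id, length),
#'   `source_counts` (true per-genome read tally), `config`, and — when
#'   `dir` is given — `paths`.
#' @export
simulate_hits <- function(config, dir = NULL) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  K <- length(config$genomes)
  n <- config$n_reads
  read_id <- sprintf("r%07d", seq_len(n))
  src <- sample.int(K, n, replace = TRUE, prob = config$pi)
  L <- pmax(35L, as.integer(round(rnorm(n, config$read_length_mean,
                                        config$read_length_sd))))
  x_src <- rbinom(n, L, 1 - config$p)
  no_hit <- runif(n) < config$no_hit_prob
  keep_src <- !no_hit & x_src >= 1L
  hits <- data.frame(read_id = read_id[keep_src],
                     genome_id = config$genomes[src[keep_src]],
                     aln_length = L[keep_src], n_ident = x_src[keep_src],
                     stringsAsFactors = FALSE)
  if (config$cross_hit_prob > 0 && K > 1L) {
    cnt <- rbinom(n, K - 1L, config$cross_hit_prob)
    cnt[no_hit] <- 0L
    tot <- sum(cnt)
    if (tot > 0L) {
      r <- rep.int(seq_len(n), cnt)
      g <- sample.int(K, tot, replace = TRUE)
      ok <- g != src[r]
      r <- r[ok]; g <- g[ok]
      xc <- x_src[r] - rpois(length(r), config$cross_hit_penalty)
      ok2 <- xc >= 1L
      r <- r[ok2]; g <- g[ok2]; xc <- xc[ok2]
      dup <- duplicated(paste(r, g))
      cross <- data.frame(read_id = read_id[r[!dup]],
                          genome_id = config$genomes[g[!dup]],
                          aln_length = L[r[!dup]],
                          n_ident = as.integer(xc[!dup]),
                          stringsAsFactors = FALSE)
      hits <- rbind(hits, cross)
    }
  }
  hits <- hits[order(match(hits$read_id, read_id)), ]
  rownames(hits) <- NULL
  class(hits) <- c("taxmix_hits", "data.frame")
  truth <- data.frame(read_id = read_id, genome_id = config$genomes[src],
                      stringsAsFactors = FALSE)
  taxonomy <- .synthetic_lineage(config$genomes, config$genus_size,
                                 config$family_size)
  lengths <- data.frame(taxon_id = config$genomes,
                        length = unname(config$genome_lengths),
                        stringsAsFactors = FALSE)
  out <- list(hits = hits, truth = truth, taxonomy = taxonomy,
              lengths = lengths,
              source_counts = setNames(tabulate(src, K), config$genomes),
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(hits = file.path(dir, "hits.tsv"),
                  taxonomy = file.path(dir, "taxonomy.tsv"),
                  lengths = file.path(dir, "genome_lengths.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_hits_tabular(hits, paths$hits)
    write.table(taxonomy, paths$taxonomy, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(lengths, paths$lengths, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  class(out) <- "taxmix_sim"
  out
}

#' @export
print.taxmix_sim <- function(x, ...) {
  print(x$config)
  cat(sprintf("  emitted %d hits for %d of %d reads\n",
              nrow(x$hits), length(unique(x$hits$read_id)), x$config$n_reads))
  invisible(x)
}

#' Write a hit table in 13-column tabular format
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore nident — the standard 12-column tabular hit format
#' with the identical-match count appended, matching the default
#' [hit_dialect()]. Unmodelled columns carry placeholder values.
#'
#' @param hits a hit table.
#' @param path output TSV path.
#' @export
write_hits_tabular <- function(hits, path) {
  df <- data.frame(hits$read_id, hits$genome_id,
                   sprintf("%.2f", 100 * hits$n_ident / hits$aln_length),
                   hits$aln_length, hits$aln_length - hits$n_ident, 0L,
                   1L, hits$aln_length, 1L, hits$aln_length,
                   "1e-30", 2L * hits$n_ident, hits$n_ident)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Benchmark community presets
#'
#' Four presets mirror the standard low/medium/high/super-high complexity
#' benchmark communities: 2, 9, 11 and 100 genomes, 150,000 reads of mean
#' length 100 bp, per-base mismatch probability 0.027. The two-genome
#' low-complexity preset uses the published source split of 25,926 vs
#' 124,074 reads and the chromosome lengths of the two organisms it is
#' modelled on (4,641,652 and 2,478,101 bp); the medium-complexity preset
#' uses log-spaced (ratio 2) proportions standing in for "diverse
#' abundance"; the high and super-high presets use equal proportions.
#' No-hit probabilities (0.0206, 0.0300, 0.0289, 0.0310) reproduce the
#' benchmark fractions of reads without database hits.
#'
#' @param name one of `"simLC-like"`, `"simMC-like"`, `"simHC-like"`,
#'   `"simSC-like"`.
#' @param seed RNG seed stored in the config.
#' @return a [community_config()].
#' @export
preset_community <- function(name = c("simLC-like", "simMC-like",
                                      "simHC-like", "simSC-like"),
                             seed = 1L) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown preset '", name[1L],
                          "'; available: simLC-like, simMC-like, ",
                          "simHC-like, simSC-like", call. = FALSE))
  switch(name,
    "simLC-like" = community_config(
      genomes = c("g001", "g002"),
      pi = c(25926, 124074) / 150000, p = 0.027, n_reads = 150000L,
      genome_lengths = c(4641652, 2478101), no_hit_prob = 0.0206,
      seed = seed),
    "simMC-like" = {
      w <- 2^(0:8)
      community_config(genomes = 9L, pi = w / sum(w), p = 0.027,
                       n_reads = 150000L, no_hit_prob = 0.0300, seed = seed)
    },
    "simHC-like" = community_config(genomes = 11L, p = 0.027,
                                    n_reads = 150000L, no_hit_prob = 0.0289,
                                    seed = seed),
    "simSC-like" = community_config(genomes = 100L, p = 0.027,
                                    n_reads = 150000L, no_hit_prob = 0.0310,
                                    seed = seed))
}
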