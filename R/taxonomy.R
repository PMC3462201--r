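#' Load a taxonomy tree
#'
#' Accepts either a plain 4-column TSV with header
#' `taxon_id  parent_id  rank  name`, or the NCBI taxonomy dump pair
#' (`nodes.dmp` + `names.dmp`, pipe-and-tab delimited; scientific names
#' only). The root encodes itself as its own parent (NCBI convention).
#' Rank labels are lower-cased and "superkingdom" is treated as "kingdom".
#' Cycles and orphan parents are rejected.
#'
#' @param path TSV path, or the `nodes.dmp` path when `format = "ncbi"`.
#' @param format `"tsv"` or `"ncbi"`.
#' @param names_path `names.dmp` path for `format = "ncbi"`; defaults to
#'   `names.dmp` next to `path`.
#' @return an object of class `taxonomy`: named vectors `parent`, `rank`,
#'   `name` indexed by taxon id, plus `root`.
#' @export
read_taxonomy <- function(path, format = c("tsv", "ncbi"), names_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  if (format == "tsv") {
    df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                     comment.char = "", colClasses = "character",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 4L)
      stop("taxonomy TSV needs 4 columns: taxon_id, parent_id, rank, name")
    names(df)[1:4] <- c("taxon_id", "parent_id", "rank", "name")
  } else {
    if (is.null(names_path))
      names_path <- file.path(dirname(path), "names.dmp")
    nodes <- strsplit(readLines(path), "\t\\|\t?")
    df <- data.frame(taxon_id = vapply(nodes, `[`, "", 1L),
                     parent_id = vapply(nodes, `[`, "", 2L),
                     rank = vapply(nodes, `[`, "", 3L),
                     name = NA_character_, stringsAsFactors = FALSE)
    nm <- strsplit(readLines(names_path), "\t\\|\t?")
    cls <- vapply(nm, `[`, "", 4L)
    sci <- grepl("scientific name", cls)
    nm_id <- vapply(nm, `[`, "", 1L)[sci]
    nm_name <- vapply(nm, `[`, "", 2L)[sci]
    df$name <- nm_name[match(df$taxon_id, nm_id)]
    df$name[is.na(df$name)] <- df$taxon_id[is.na(df$name)]
  }
  build_taxonomy(df)
}

#' Build a taxonomy tree from a node table
#'
#' @param df data.frame with columns taxon_id, parent_id, rank, name.
#' @return a `taxonomy` object; see [read_taxonomy()].
#' @export
build_taxonomy <- function(df) {
  stopifnot(all(c("taxon_id", "parent_id", "rank", "name") %in% names(df)))
  id <- as.character(df$taxon_id)
  if (anyDuplicated(id)) stop("duplicate taxon ids in taxonomy")
  parent <- setNames(as.character(df$parent_id), id)
  rk <- tolower(as.character(df$rank))
  rk[rk == "superkingdom"] <- "kingdom"
  rank <- setNames(rk, id)
  name <- setNames(as.character(df$name), id)
  orphan <- setdiff(parent, id)
  if (length(orphan))
    stop("parent id(s) not present as taxa: ", paste(head(orphan, 5L), collapse = ", "))
  roots <- id[parent[id] == id]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one self-parent root; found ", length(roots))
  # cycle check: follow parents; every walk must reach the root in <= n steps
  n <- length(id)
  for (start in id) {
    cur <- start
    for (step in seq_len(n + 1L)) {
      if (cur == roots) break
      cur <- parent[[cur]]
      if (step > n)
        stop("cycle detected in taxonomy involving taxon ", start)
    }
    if (cur != roots) stop("cycle detected in taxonomy involving taxon ", start)
  }
  structure(list(parent = parent, rank = rank, name = name, root = roots),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy:", length(x$parent), "taxa, root =", x$root, "\n")
  rk <- table(x$rank)
  cat("  ranks:", paste(sprintf("%s(%d)", names(rk), rk), collapse = ", "), "\n")
  invisible(x)
}

#' Ancestor of a taxon at a named rank
#'
#' Walks parent links from each query taxon upward and returns the ancestor
#' whose rank equals `rank`, or `NA` when the lineage skips that rank.
#' Unranked nodes ("no rank", e.g. NCBI strains) are traversed transparently,
#' so a strain resolves to its species, genus, family, and so on. Querying a
#' node at its own rank returns the node itself.
#'
#' @param taxonomy a [read_taxonomy()] tree.
#' @param taxa character vector of taxon ids (all must be in the tree).
#' @param rank rank label, e.g. "species", "genus".
#' @return character vector of ancestor taxon ids (NA where absent).
#' @export
ancestor_at_rank <- function(taxonomy, taxa, rank) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  taxa <- as.character(taxa)
  unknown <- setdiff(taxa, names(taxonomy$parent))
  if (length(unknown))
    stop("unknown taxon id(s): ", paste(head(unknown, 5L), collapse = ", "))
  rank <- tolower(rank)
  if (rank == "superkingdom") rank <- "kingdom"
  out <- rep(NA_character_, length(taxa))
  cache <- new.env(parent = emptyenv())
  for (k in seq_along(taxa)) {
    t0 <- taxa[k]
    hit <- cache[[t0]]
    if (!is.null(hit)) { out[k] <- hit; next }
    cur <- t0
    res <- NA_character_
    repeat {
      if (taxonomy$rank[[cur]] == rank) { res <- cur; break }
      nxt <- taxonomy$parent[[cur]]
      if (nxt == cur) break                  # reached root without the rank
      cur <- nxt
    }
    cache[[t0]] <- res
    out[k] <- res
  }
  out
}

#' Summarise read assignments at each taxonomic rank
#'
#' Credits each genome-level assignment to its ancestors: a read assigned to
#' a strain counts towards that strain's species, genus, family and every
#' higher rank present in its lineage. Reads whose lineage skips a rank are
#' omitted from that rank, so per-rank counts sum to at most the number of
#' assigned reads.
#'
#' @param assignment a `taxmix_assignment` from [assign_reads()].
#' @param taxonomy a [read_taxonomy()] tree resolving every assigned genome.
#' @param ranks ranks to report, lowest first.
#' @return a data.frame of class `taxmix_ranks`: rank, taxon_id, name,
#'   reads, proportion (of assigned reads).
#' @export
rollup <- function(assignment, taxonomy,
                   ranks = c("species", "genus", "family", "order",
                             "class", "phylum", "kingdom")) {
  stopifnot(inherits(assignment, "taxmix_assignment"),
            inherits(taxonomy, "taxonomy"))
  genomes <- names(assignment$counts)
  unknown <- setdiff(genomes, names(taxonomy$parent))
  if (length(unknown))
    stop("assigned genome(s) missing from taxonomy: ",
         paste(head(unknown, 5L), collapse = ", "))
  n <- assignment$n
  out <- vector("list", length(ranks))
  for (k in seq_along(ranks)) {
    anc <- ancestor_at_rank(taxonomy, genomes, ranks[k])
    keep <- !is.na(anc)
    cnt <- rowsum(assignment$counts[keep], anc[keep], reorder = TRUE)
    taxon <- rownames(cnt)
    out[[k]] <- data.frame(rank = ranks[k], taxon_id = taxon,
                           name = unname(taxonomy$name[taxon]),
                           reads = as.integer(cnt[, 1L]),
                           proportion = cnt[, 1L] / n,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$rank, ranks), -res$reads), ]
  rownames(res) <- NULL
  class(res) <- c("taxmix_ranks", "data.frame")
  res
}
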