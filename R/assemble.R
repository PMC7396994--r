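# De Bruijn graph assembler with multi-k iteration and trusted/untrusted
# contig seeding. K-mers are counted on both read strands and orientation is
# fixed downstream by the G-content rule, so the graph holds both a contig
# and its reverse complement; extraction deduplicates them. Trusted-contig
# k-mers are exempt from the coverage prune (this is how the reference
# rescues under-covered samples in later assembly rounds); untrusted-contig
# k-mers only add a pseudo-count of 1 and remain prunable.

#' Assembly parameters
#'
#' @param k_list ascending odd k values; all must be below the read length.
#' @param min_kmer_count edges seen fewer times are pruned unless trusted
#'   (default 3).
#' @param trusted_contigs,untrusted_contigs seed sequences (see module notes).
#' @param tip_length_factor tips shorter than `tip_length_factor * k` bases
#'   are clipped (default 2).
#' @param bubble_max_divergence parallel branches whose lengths differ by at
#'   most this many bases are collapsed to the higher-coverage branch
#'   (default 3).
#' @return an `assembly_params` object.
#' @export
assembly_params <- function(k_list = c(21L, 33L, 55L, 77L, 99L, 127L),
                            min_kmer_count = 3L,
                            trusted_contigs = character(),
                            untrusted_contigs = character(),
                            tip_length_factor = 2L,
                            bubble_max_divergence = 3L) {
  k_list <- as.integer(k_list)
  if (any(k_list %% 2L == 0L)) stop("k values must be odd")
  if (is.unsorted(k_list, strictly = TRUE)) stop("k_list must be strictly ascending")
  if (min_kmer_count < 1L) stop("min_kmer_count must be >= 1")
  structure(list(k_list = k_list, min_kmer_count = as.integer(min_kmer_count),
                 trusted_contigs = trusted_contigs,
                 untrusted_contigs = untrusted_contigs,
                 tip_length_factor = as.integer(tip_length_factor),
                 bubble_max_divergence = as.integer(bubble_max_divergence)),
            class = "assembly_params")
}

#' Count k-mers of reads (both strands)
#'
#' @param reads character vector of reads.
#' @param k odd integer >= 11, at most the read length.
#' @return a `kmer_table`: list with `kmer` and `count`, attribute `k`.
#' @export
count_kmers <- function(reads, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L) stop("k must be odd and >= 11")
  tab <- if (length(reads)) cpp_count_kmers(reads, k)
         else list(kmer = character(0), count = integer(0))
  structure(tab, class = "kmer_table", k = k)
}

# k-mers of a set of contig sequences (both strands, presence only)
.contig_kmers <- function(contigs, k) {
  contigs <- contigs[nchar(contigs) >= k]
  if (length(contigs) == 0L) return(character(0))
  cpp_count_kmers(contigs, k)$kmer
}

#' Build a pruned de Bruijn graph from a k-mer table
#'
#' Edges with count below `min_kmer_count` are removed unless they belong to
#' a trusted contig; untrusted-contig k-mers enter with a pseudo-count of 1
#' (added to any read support) and stay subject to the prune.
#'
#' @param table a `kmer_table`.
#' @param params an `assembly_params`.
#' @return a `dbg` object: data.frame with columns kmer, count, trusted.
#' @export
build_graph <- function(table, params) {
  k <- attr(table, "k")
  kmer <- table$kmer
  count <- table$count
  untr <- .contig_kmers(params$untrusted_contigs, k)
  if (length(untr)) {
    idx <- match(untr, kmer)
    new <- is.na(idx)
    count[idx[!new]] <- count[idx[!new]] + 1L
    kmer <- c(kmer, untr[new])
    count <- c(count, rep(1L, sum(new)))
  }
  tru <- .contig_kmers(params$trusted_contigs, k)
  trusted <- kmer %in% tru
  if (length(tru)) {
    new <- !(tru %in% kmer)
    kmer <- c(kmer, tru[new])
    count <- c(count, rep(1L, sum(new)))
    trusted <- c(trusted, rep(TRUE, sum(new)))
  }
  keep <- trusted | count >= params$min_kmer_count
  g <- data.frame(kmer = kmer[keep], count = count[keep],
                  trusted = trusted[keep], stringsAsFactors = FALSE)
  g <- g[order(g$kmer), , drop = FALSE]     # deterministic edge order
  rownames(g) <- NULL
  structure(g, class = c("dbg", "data.frame"), k = k)
}

# maximal non-branching paths; returns list of integer edge-index vectors
.extract_unitigs <- function(kmers, k) {
  nE <- length(kmers)
  if (nE == 0L) return(list())
  pre <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  nodes <- unique(c(pre, suf))
  pe <- match(pre, nodes)
  se <- match(suf, nodes)
  nN <- length(nodes)
  outdeg <- tabulate(pe, nN)
  indeg <- tabulate(se, nN)
  simple <- outdeg == 1L & indeg == 1L
  oe <- rep(NA_integer_, nN)
  single_out <- which(outdeg[pe] == 1L)
  oe[pe[single_out]] <- single_out
  used <- logical(nE)
  paths <- vector("list", nE)
  np <- 0L
  walk <- function(e0) {
    path <- integer(64L); n <- 0L
    e <- e0
    repeat {
      used[e] <<- TRUE
      n <- n + 1L
      if (n > length(path)) path <- c(path, integer(length(path)))
      path[n] <- e
      nx <- se[e]
      if (!simple[nx]) break
      e2 <- oe[nx]
      if (is.na(e2) || used[e2]) break
      e <- e2
    }
    path[seq_len(n)]
  }
  for (e in seq_len(nE)) {
    if (used[e] || simple[pe[e]]) next
    np <- np + 1L
    paths[[np]] <- walk(e)
  }
  for (e in seq_len(nE)) {        # leftover simple cycles
    if (used[e]) next
    np <- np + 1L
    paths[[np]] <- walk(e)
  }
  list(paths = paths[seq_len(np)], pe = pe, se = se, nodes = nodes,
       indeg = indeg, outdeg = outdeg)
}

.unitig_seq <- function(kmers, path, k, nodes, pe) {
  paste0(nodes[pe[path[1L]]],
         paste(substr(kmers[path], k, k), collapse = ""))
}

#' Simplify a graph and extract contigs
#'
#' Clips tips (dead-ended unitigs shorter than `tip_length_factor * k`), pops
#' simple bubbles (parallel unitigs between the same nodes, length difference
#' at most `bubble_max_divergence`; the higher-coverage branch is kept, ties
#' broken lexicographically), then emits maximal non-branching paths as
#' contigs in descending (length, coverage) order with SPAdes-style ids.
#' Reverse-complement twins arising from two-strand counting are reported
#' once, as the lexicographically smaller orientation.
#'
#' @param graph a `dbg`.
#' @param params an `assembly_params`.
#' @return a `contig_set` data.frame: id, seq, length, mean_cov.
#' @export
simplify_and_extract <- function(graph, params = assembly_params()) {
  k <- attr(graph, "k")
  kmers <- graph$kmer
  counts <- graph$count
  tip_len <- params$tip_length_factor * k
  div <- params$bubble_max_divergence

  for (iter in 1:8) {
    if (length(kmers) == 0L) break
    u <- .extract_unitigs(kmers, k)
    if (length(u$paths) == 0L) break
    starts <- vapply(u$paths, function(p) u$pe[p[1L]], integer(1))
    ends <- vapply(u$paths, function(p) u$se[p[length(p)]], integer(1))
    lens <- vapply(u$paths, length, integer(1)) + (k - 1L)
    covs <- vapply(u$paths, function(p) mean(counts[p]), numeric(1))
    dead_start <- u$indeg[starts] == 0L
    dead_end <- u$outdeg[ends] == 0L
    is_tip <- xor(dead_start, dead_end) & lens < tip_len
    drop <- which(is_tip)
    if (length(drop) == 0L) {
      # bubble popping: parallel unitigs between identical node pairs
      key <- paste(starts, ends)
      for (g in split(seq_along(u$paths), key)) {
        if (length(g) < 2L) next
        seqs <- vapply(g, function(i)
          .unitig_seq(kmers, u$paths[[i]], k, u$nodes, u$pe), character(1))
        ord <- g[order(-covs[g], seqs)]
        keepi <- ord[1L]
        for (i in ord[-1L])
          if (abs(lens[i] - lens[keepi]) <= div) drop <- c(drop, i)
      }
    }
    if (length(drop) == 0L) break
    rm_edges <- unlist(u$paths[drop])
    kmers <- kmers[-rm_edges]
    counts <- counts[-rm_edges]
  }

  if (length(kmers) == 0L)
    return(structure(data.frame(id = character(0), seq = character(0),
                                length = integer(0), mean_cov = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("contig_set", "data.frame")))
  u <- .extract_unitigs(kmers, k)
  seqs <- vapply(u$paths, function(p) .unitig_seq(kmers, p, k, u$nodes, u$pe),
                 character(1))
  covs <- vapply(u$paths, function(p) mean(counts[p]), numeric(1))
  rcs <- revcomp(seqs)
  canon <- ifelse(seqs <= rcs, seqs, rcs)
  keep <- !duplicated(canon)
  df <- data.frame(seq = pmin(seqs, rcs)[keep], length = nchar(seqs)[keep],
                   mean_cov = covs[keep], stringsAsFactors = FALSE)
  df <- df[order(-df$length, -df$mean_cov, df$seq), , drop = FALSE]
  df$id <- sprintf("NODE_%d_length_%d_cov_%.4f",
                   seq_len(nrow(df)), df$length, df$mean_cov)
  rownames(df) <- NULL
  structure(df[, c("id", "seq", "length", "mean_cov")],
            class = c("contig_set", "data.frame"))
}

#' Multi-k iterative assembly
#'
#' Runs one assembly per k in ascending order; contigs from each iteration
#' are fed to the next as untrusted contigs, while externally supplied
#' trusted/untrusted contigs participate at every k. Returns the final-k
#' contig list.
#'
#' @param reads character vector of reads (both mates, any orientation).
#' @param params an `assembly_params`.
#' @return a `contig_set`.
#' @export
assemble_multi_k <- function(reads, params = assembly_params()) {
  if (length(reads) == 0L && length(params$trusted_contigs) == 0L)
    return(structure(data.frame(id = character(0), seq = character(0),
                                length = integer(0), mean_cov = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("contig_set", "data.frame")))
  prev <- character(0)
  contigs <- NULL
  for (k in params$k_list) {
    tab <- count_kmers(reads, k)
    p_k <- params
    p_k$untrusted_contigs <- c(params$untrusted_contigs, prev)
    g <- build_graph(tab, p_k)
    contigs <- simplify_and_extract(g, params)
    prev <- head(contigs$seq, 20L)
  }
  contigs
}

#' Write contigs as FASTA in the NODE id dialect
#'
#' @param contigs a `contig_set`.
#' @param path output path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(contigs))
    writeLines(paste0(">", contigs$id, "\n", contigs$seq), con)
  invisible(path)
}

#' Read contigs from a NODE-dialect FASTA
#'
#' @param path FASTA path with `NODE_<i>_length_<L>_cov_<C>` headers.
#' @return a `contig_set`.
#' @export
read_contigs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- names(x)
  m <- regmatches(ids, regexec("NODE_\\d+_length_(\\d+)_cov_([0-9.]+)", ids))
  lens <- vapply(m, function(g) as.integer(g[2]), integer(1))
  covs <- vapply(m, function(g) as.numeric(g[3]), numeric(1))
  structure(data.frame(id = ids, seq = as.character(unname(x)),
                       length = lens, mean_cov = covs, stringsAsFactors = FALSE),
            class = c("contig_set", "data.frame"))
}
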