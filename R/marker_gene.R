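#' Pairwise 16S rRNA percent identity
#'
#' Global (Needleman-Wunsch) alignment of two nucleotide sequences with
#' affine gap penalties, followed by percent identity computed as matches
#' divided by aligned columns, excluding terminal-gap columns (internal gap
#' columns count against identity). If the identity in the given orientation
#' falls below `orient_threshold`, the reverse complement of the second
#' sequence is tried and used when it scores higher — the orientation check
#' applied before clustering Sanger reads.
#'
#' @param a,b Character strings or named character vectors (DNA, IUPAC
#'   codes).
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring
#'   (defaults 1, -1, 2, 0.5; penalties are positive costs). Identity values
#'   for near-identical full-length 16S sequences are insensitive to these.
#' @param check_orientation Try the reverse complement when identity falls
#'   below `orient_threshold` (default `TRUE`).
#' @param orient_threshold Identity (percent) below which the reverse
#'   complement is tried. Global-alignment identity between unrelated
#'   nucleotide sequences sits near 50-55% (gaps let a quarter of random
#'   columns match), so the cutoff defaults to 60 to leave a margin above
#'   that floor; any related pair in the correct orientation scores far
#'   higher.
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_opening = 2, gap_extension = 0.5,
                              check_orientation = TRUE, orient_threshold = 60) {
  a <- as.character(a)[1]; b <- as.character(b)[1]
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (identical(a, b)) return(100)
  pid <- alignment_identity(a, b, match, mismatch, gap_opening, gap_extension)
  if (check_orientation && pid < orient_threshold) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    pid_rc <- alignment_identity(a, rc, match, mismatch, gap_opening, gap_extension)
    if (pid_rc > pid) pid <- pid_rc
  }
  pid
}

alignment_identity <- function(a, b, match, mismatch, gap_opening, gap_extension) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_opening,
                                      gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  n <- length(pa)
  # trim terminal-gap columns on either end
  non_gap <- pa != "-" & pb != "-"
  first <- which(non_gap)[1]
  last <- utils::tail(which(non_gap), 1)
  if (is.na(first)) return(0)
  cols <- first:last
  100 * sum(pa[cols] == pb[cols]) / length(cols)
}

#' Threshold-based 16S taxonomy call against a type-strain reference set
#'
#' The query is compared with every reference; the best hit (ties broken by
#' reference id) determines the call level using the conventional
#' full-length 16S thresholds: identity >= 98.7% gives a species-level call,
#' identity > 95% (but below 98.7%) a genus-level call, and anything at or
#' below 95% is unclassified.
#'
#' @param query Character string (or named length-1 vector) of the query
#'   sequence.
#' @param refs Named character vector of reference sequences (e.g. from
#'   [read_fasta()]), or a `DNAStringSet`.
#' @param query_id Label carried into the call.
#' @param species_threshold,genus_threshold Identity thresholds (defaults
#'   98.7 and 95).
#' @param ... Passed to [pairwise_identity()].
#' @return List of class `taxonomy_call`: `query_id`, `best_ref_id`,
#'   `percent_identity`, `level`, plus `identities` (all reference
#'   identities).
#' @export
classify_16s <- function(query, refs, query_id = NA_character_,
                         species_threshold = 98.7, genus_threshold = 95, ...) {
  refs <- as_named_sequences(refs)
  if (!length(refs)) stop("reference set is empty")
  ids <- vapply(names(refs), function(id)
    pairwise_identity(query, refs[[id]], ...), numeric(1))
  ord <- order(-ids, names(refs))
  best <- ord[1]
  pid <- ids[best]
  level <- if (pid >= species_threshold) "species"
           else if (pid > genus_threshold) "genus"
           else "unclassified"
  structure(list(query_id = query_id,
                 best_ref_id = names(refs)[best],
                 percent_identity = unname(pid),
                 level = level,
                 identities = ids),
            class = "taxonomy_call")
}

#' @export
print.taxonomy_call <- function(x, ...) {
  cat(sprintf("taxonomy_call %s: %s (%.2f%% to %s)\n", x$query_id, x$level,
              x$percent_identity, x$best_ref_id))
  invisible(x)
}

as_named_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be named")
  as.list(x)
}

#' Cluster 16S sequences into OTUs
#'
#' Pairwise distances (1 - identity/100) are clustered agglomeratively with
#' average linkage and the tree is cut at `1 - similarity` (default 0.01,
#' i.e. 99% OTUs). Each cluster's representative is the member minimizing
#' the summed distance to the rest of its cluster, with ties broken by id —
#' the usual representative-sequence rule.
#'
#' @param seqs Named character vector of sequences (or `DNAStringSet`).
#' @param similarity Similarity threshold as a fraction (default 0.99).
#' @param ... Passed to [pairwise_identity()].
#' @return Object of class `otu_set`: `threshold`, `clusters` (list of member
#'   id vectors), `representatives` (one id per cluster), `distances`
#'   (square matrix).
#' @export
cluster_otus <- function(seqs, similarity = 0.99, ...) {
  seqs <- as_named_sequences(seqs)
  n <- length(seqs)
  if (n < 1L) stop("at least one sequence is required")
  ids <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dij <- 1 - pairwise_identity(seqs[[i]], seqs[[j]], ...) / 100
      d[i, j] <- dij; d[j, i] <- dij
    }
  }
  membership <- if (n == 1L) stats::setNames(1L, ids) else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    stats::cutree(hc, h = 1 - similarity)
  }
  clusters <- split(ids, membership)
  names(clusters) <- NULL
  # stable ordering: by smallest member id
  clusters <- clusters[order(vapply(clusters, function(m) sort(m)[1], character(1)))]
  reps <- vapply(clusters, function(members) {
    if (length(members) == 1L) return(members)
    tot <- rowSums(d[members, members, drop = FALSE])
    members[order(tot, members)][1]
  }, character(1))
  structure(list(threshold = similarity, clusters = clusters,
                 representatives = reps, distances = d),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("otu_set: %d OTUs from %d sequences at %.0f%% similarity\n",
              length(x$clusters), nrow(x$distances), 100 * x$threshold))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration with two determinism/robustness
#' conventions: ties in the Q criterion are broken by the lexicographically
#' smallest pair of labels, and a negative branch length is clamped to zero
#' with the deficit transferred to its sister branch (preserving the path
#' length between the joined taxa).
#'
#' @param d Square symmetric numeric matrix with zero diagonal and row/column
#'   labels; at least 3 taxa.
#' @return Object of class `nj_tree`: `phylo` (ape tree), `newick`.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  if (n < 3L) stop("at least 3 taxa are required")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  dimnames(d) <- list(labels, labels)
  # each active node carries a newick fragment
  frag <- stats::setNames(labels, labels)
  active <- labels
  while (length(active) > 3L) {
    m <- length(active)
    dm <- d[active, active]
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    # lexicographically smallest (sorted) label pair
    pair_lab <- t(apply(best, 1, function(ij) sort(active[ij])))
    pick <- order(pair_lab[, 1], pair_lab[, 2])[1]
    i <- pair_lab[pick, 1]; j <- pair_lab[pick, 2]
    vi <- 0.5 * dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dm[i, j] - vi
    bl <- clamp_branch_pair(vi, vj)
    new_lab <- paste0("(", i, ")(", j, ")")
    frag[new_lab] <- sprintf("(%s:%.10g,%s:%.10g)", frag[[i]], bl[1], frag[[j]], bl[2])
    others <- setdiff(active, c(i, j))
    dn <- 0.5 * (dm[i, others] + dm[j, others] - dm[i, j])
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_lab
    d[new_lab, others] <- dn; d[others, new_lab] <- dn
    active <- c(others, new_lab)
  }
  # terminal 3-star
  a <- sort(active)
  da <- d[a, a]
  va <- (da[a[1], a[2]] + da[a[1], a[3]] - da[a[2], a[3]]) / 2
  vb <- (da[a[1], a[2]] + da[a[2], a[3]] - da[a[1], a[3]]) / 2
  vc <- (da[a[1], a[3]] + da[a[2], a[3]] - da[a[1], a[2]]) / 2
  v <- pmax(c(va, vb, vc), 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frag[[a[1]]], v[1], frag[[a[2]]], v[2], frag[[a[3]]], v[3])
  phy <- ape::read.tree(text = newick)
  structure(list(phylo = phy, newick = newick), class = "nj_tree")
}

clamp_branch_pair <- function(vi, vj) {
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- vi + vj; vj <- 0 }
  c(max(vi, 0), max(vj, 0))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Destination file.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_named_sequences(seqs)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path, width = 80L)
  invisible(path)
}
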