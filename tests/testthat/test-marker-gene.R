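random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, positions) {
  s <- strsplit(seq, "")[[1]]
  for (p in positions) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

test_that("pairwise identity counts mismatches and is symmetric", {
  a <- random_seq(100, 1)
  expect_equal(pairwise_identity(a, a), 100)
  b <- mutate_at(a, c(10, 60))
  expect_equal(pairwise_identity(a, b), 98)
  expect_equal(pairwise_identity(b, a), pairwise_identity(a, b))
  expect_error(pairwise_identity("", a), "non-empty")
})

test_that("orientation is auto-corrected for reverse-complement input", {
  a <- random_seq(300, 2)
  expect_equal(pairwise_identity(a, revcomp(a)), 100)
  b <- mutate_at(a, c(5, 150))
  expect_equal(pairwise_identity(a, revcomp(b)), pairwise_identity(a, b),
               tolerance = 0.2)
})

test_that("taxonomy calls follow the 98.7 / 95 identity thresholds", {
  ref <- random_seq(1000, 3)
  refs <- c("Bacillus alpha" = ref,
            "Bacillus beta" = mutate_at(ref, seq(1, 991, by = 10)))
  exact <- classify_16s(ref, refs, query_id = "q1")
  expect_equal(exact$level, "species")
  expect_equal(exact$percent_identity, 100)
  expect_equal(exact$best_ref_id, "Bacillus alpha")

  q96 <- mutate_at(ref, seq(3, 3 + 39 * 25, by = 25))  # 40 subs / 1000 nt
  call96 <- classify_16s(q96, refs["Bacillus alpha"])
  expect_equal(call96$percent_identity, 96, tolerance = 0.2)
  expect_equal(call96$level, "genus")

  q94 <- mutate_at(ref, seq(2, 2 + 59 * 16, by = 16))  # 60 subs / 1000 nt
  call94 <- classify_16s(q94, refs["Bacillus alpha"])
  expect_equal(call94$percent_identity, 94, tolerance = 0.3)
  expect_equal(call94$level, "unclassified")
  expect_error(classify_16s(ref, character(0)), "empty|named")
})

test_that("OTU clustering at 99% merges near-identical sequences only", {
  base <- random_seq(1000, 4)
  seqs <- c(A = base, B = mutate_at(base, c(7, 300, 701, 850, 990)),
            C = mutate_at(base, seq(4, 4 + 99 * 10, by = 10)))
  otus <- cluster_otus(seqs, similarity = 0.99)
  expect_length(otus$clusters, 2)
  sizes <- sort(vapply(otus$clusters, length, integer(1)))
  expect_equal(sizes, c(1L, 2L))
  expect_true(setequal(otus$clusters[[1]], c("A", "B")) ||
              setequal(otus$clusters[[2]], c("A", "B")))

  # identical sequences collapse to one OTU; similarity 1 keeps unique ones
  same <- c(x = base, y = base, z = base)
  expect_length(cluster_otus(same, 0.99)$clusters, 1)
  expect_length(cluster_otus(seqs, 1e-9)$clusters, 1)
})

test_that("OTU representatives minimize total within-cluster distance", {
  base <- random_seq(600, 5)
  # B sits between A and C, so it minimizes the summed distance
  seqs <- c(A = mutate_at(base, 1:4),
            B = base,
            C = mutate_at(base, 301:304))
  otus <- cluster_otus(seqs, similarity = 0.97)
  expect_length(otus$clusters, 1)
  d <- otus$distances
  brute <- names(which.min(rowSums(d)))
  expect_equal(unname(otus$representatives[1]), brute)
  expect_equal(brute, "B")
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 2, 3,
                2, 0, 3,
                3, 3, 0), 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- nj_tree(d)$phylo
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 2)
})

test_that("neighbor joining recovers additive 4- and 5-taxon trees", {
  # additive matrix from tree ((A:1,B:2):1,(C:3,D:1)); internal edge 1
  d4 <- matrix(c(0, 3, 5, 3,
                 3, 0, 6, 4,
                 5, 6, 0, 4,
                 3, 4, 4, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d4)$phylo
  # recovered tree must reproduce the generating distances exactly
  dm <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(dm, d4, tolerance = 1e-9)
  # and agree with the reference implementation on topology
  ref <- ape::nj(as.dist(d4))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)

  set.seed(6)
  ref_tree <- ape::rtree(5)
  d5 <- ape::cophenetic.phylo(ref_tree)
  tr5 <- nj_tree(d5)$phylo
  expect_equal(ape::dist.topo(ape::unroot(tr5), ape::unroot(ref_tree)), 0,
               ignore_attr = TRUE)
  dm5 <- ape::cophenetic.phylo(tr5)[rownames(d5), colnames(d5)]
  expect_equal(dm5, d5, tolerance = 1e-9)
})

test_that("degenerate distance matrices give star trees and bad input errors", {
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d0)$phylo
  expect_true(all(tr$edge.length == 0))
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(bad), "3 taxa|symmetric")
  asym <- matrix(c(0, 1, 2, 3, 0, 4, 2, 4, 0), 3, 3)
  expect_error(nj_tree(asym), "symmetric")
})

test_that("fasta i/o round-trips named sequence sets", {
  seqs <- c("Bacillus alpha" = random_seq(80, 7),
            "Bacillus beta" = random_seq(90, 8))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(unname(back), unname(seqs))
  expect_identical(names(back), names(seqs))
})
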