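#' Bin a peak list or MSP onto a fixed m/z grid
#'
#' Peak intensities are summed into half-open bins `[lo, hi)` of width
#' `bin_width` spanning `[mass_lo, mass_hi)`; peaks outside the range are
#' dropped and the result is total-normalized (sums to 1 whenever any peak
#' falls in range). The default mass window, 3,000-12,000 m/z, is the range
#' conventionally used for composite correlation index analysis; it is
#' narrower than the full peak-picking range on purpose.
#'
#' @param p A [peak_list()] or `msp`.
#' @param mass_lo,mass_hi Mass window in Da (defaults 3000 and 12000).
#' @param bin_width Bin width in Da (default 3).
#' @return Object of class `binned_profile`: `edges` (length nbins+1),
#'   `values` (length nbins), `params`.
#' @export
bin_profile <- function(p, mass_lo = 3000, mass_hi = 12000, bin_width = 3) {
  if (inherits(p, "msp")) p <- msp_as_peaklist(p)
  stopifnot(inherits(p, "peak_list"))
  if (mass_lo >= mass_hi) stop("mass_lo must be below mass_hi")
  if (bin_width <= 0) stop("bin_width must be positive")
  nbins <- ceiling((mass_hi - mass_lo) / bin_width)
  edges <- mass_lo + bin_width * (0:nbins)
  values <- numeric(nbins)
  inside <- p$mz >= mass_lo & p$mz < mass_hi
  if (any(inside)) {
    idx <- findInterval(p$mz[inside], edges, rightmost.closed = FALSE)
    agg <- tapply(p$intensity[inside], idx, sum)
    values[as.integer(names(agg))] <- agg
    values <- values / sum(values)
  }
  structure(list(edges = edges, values = values,
                 params = list(mass_lo = mass_lo, mass_hi = mass_hi,
                               bin_width = bin_width)),
            class = "binned_profile")
}

#' Composite correlation index between two binned profiles
#'
#' The common mass range is divided into `n_intervals` contiguous blocks of
#' (as near as possible) equal size; within each block the Pearson
#' correlation of the two profiles' bin values is computed and clamped at
#' zero, and the CCI is the mean of these per-interval values. Identical
#' profiles give 1, profiles with unrelated peak support give 0, and values
#' above 0.9 are conventionally read as a strong correlation. Blocks in which
#' both profiles are constant (typically empty mass regions) contribute 1;
#' blocks where only one side is constant contribute 0.
#'
#' @param a,b [bin_profile()] results on identical grids.
#' @param n_intervals Number of interval blocks (default 10).
#' @return CCI in \[0, 1\].
#' @export
cci <- function(a, b, n_intervals = 10L) {
  stopifnot(inherits(a, "binned_profile"), inherits(b, "binned_profile"))
  if (length(a$values) != length(b$values) || !isTRUE(all.equal(a$edges, b$edges)))
    stop("profiles must share an identical bin grid")
  nb <- length(a$values)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L || n_intervals > nb)
    stop("n_intervals must be between 1 and the number of bins")
  block <- ceiling(seq_len(nb) / (nb / n_intervals))
  rs <- vapply(split(seq_len(nb), block), function(i) {
    interval_correlation(a$values[i], b$values[i])
  }, numeric(1))
  mean(pmax(0, rs))
}

interval_correlation <- function(x, y) {
  cx <- stats::sd(x) == 0; cy <- stats::sd(y) == 0
  if (cx && cy) return(1)
  if (cx || cy) return(0)
  stats::cor(x, y)
}

#' CCI matrix across strains
#'
#' Builds, for each strain, the mean of its replicates' total-normalized
#' binned profiles, then computes all pairwise composite correlation indices.
#' Every strain must contribute at least two spectra. The result is exactly
#' symmetric with unit diagonal.
#'
#' @param strains Named list; each element is a list of [peak_list()]
#'   replicates for one strain.
#' @param mass_lo,mass_hi,bin_width Binning parameters, see [bin_profile()].
#' @param n_intervals CCI intervals (default 10).
#' @return Object of class `cci_matrix`: `values` (square matrix), `labels`,
#'   `params`.
#' @export
cci_matrix <- function(strains, mass_lo = 3000, mass_hi = 12000, bin_width = 3,
                       n_intervals = 10L) {
  if (length(strains) < 2L) stop("at least two strains are required")
  if (is.null(names(strains)) || any(!nzchar(names(strains))))
    stop("strains must be a named list")
  nspec <- vapply(strains, length, integer(1))
  if (any(nspec < 2L))
    stop("strain(s) with fewer than two spectra: ",
         paste(names(strains)[nspec < 2L], collapse = ", "))
  profiles <- lapply(strains, function(reps) {
    binned <- lapply(reps, bin_profile, mass_lo = mass_lo, mass_hi = mass_hi,
                     bin_width = bin_width)
    avg <- Reduce(`+`, lapply(binned, `[[`, "values")) / length(binned)
    out <- binned[[1]]
    out$values <- avg
    out
  })
  n <- length(profiles)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- cci(profiles[[i]], profiles[[j]], n_intervals)
    m[i, j] <- v; m[j, i] <- v
  }
  dimnames(m) <- list(names(strains), names(strains))
  structure(list(values = m, labels = names(strains),
                 params = list(n_intervals = as.integer(n_intervals),
                               mass_lo = mass_lo, mass_hi = mass_hi,
                               bin_width = bin_width)),
            class = "cci_matrix")
}

#' @export
print.cci_matrix <- function(x, ...) {
  cat(sprintf("cci_matrix: %d strains, %d intervals over %g-%g m/z\n",
              length(x$labels), x$params$n_intervals,
              x$params$mass_lo, x$params$mass_hi))
  print(round(x$values, 3))
  invisible(x)
}

#' Heatmap of a CCI matrix
#'
#' Red marks high correlation (values above `annotate` indicate strong
#' within-strain similarity), blue low, matching the conventional display of
#' composite correlation indices.
#'
#' @param x A [cci_matrix()].
#' @param annotate Threshold drawn in the legend title (default 0.9).
#' @param ... Passed to [graphics::image()].
#' @export
plot_cci <- function(x, annotate = 0.9, ...) {
  stopifnot(inherits(x, "cci_matrix"))
  n <- length(x$labels)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(100)
  graphics::image(seq_len(n), seq_len(n), t(x$values[n:1, , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("CCI (>%.1f strong correlation)", annotate), ...)
  graphics::axis(1, at = seq_len(n), labels = x$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(x$labels), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Hierarchical dendrogram of spectral profiles
#'
#' Agglomerative clustering of binned profiles with Euclidean distance and
#' average linkage (UPGMA), the standard display for comparing database
#' entries. Entries are sorted by label before clustering so the result does
#' not depend on input order; newick branch lengths follow the ultrametric
#' node heights (half the merge distance).
#'
#' @param x A [spectral_library()], or a named list of [peak_list()] /
#'   `msp` objects.
#' @param mass_lo,mass_hi,bin_width Binning parameters, see [bin_profile()].
#' @return Object of class `msp_dendrogram`: `hclust` (merge table and
#'   heights), `phylo` (ape tree), `newick`.
#' @export
msp_dendrogram <- function(x, mass_lo = 3000, mass_hi = 12000, bin_width = 3) {
  if (inherits(x, "spectral_library")) x <- x$entries
  if (length(x) < 2L) stop("at least two profiles are required")
  if (is.null(names(x))) stop("profiles must be named")
  x <- x[order(names(x))]
  mat <- do.call(rbind, lapply(x, function(p)
    bin_profile(p, mass_lo, mass_hi, bin_width)$values))
  rownames(mat) <- names(x)
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy, newick = ape::write.tree(phy)),
            class = "msp_dendrogram")
}

#' @export
print.msp_dendrogram <- function(x, ...) {
  cat(sprintf("msp_dendrogram: %d leaves, max merge height %.4g\n",
              length(x$hclust$labels), max(x$hclust$height)))
  invisible(x)
}
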