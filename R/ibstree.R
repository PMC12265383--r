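#' Thin variants to a random subset
#'
#' Uniform random subset without replacement, order-preserving and
#' deterministic given the seed. Requests larger than the available site
#' count return all sites with a warning.
#'
#' @param vt variant table.
#' @param count target number of sites.
#' @param seed RNG seed.
#' @return sorted integer vector of column indices.
#' @export
thin_variants <- function(vt, count, seed) {
  V <- nrow(vt)
  if (count >= V) {
    if (count > V) warning("thin_variants: count exceeds available sites")
    return(seq_len(V))
  }
  set.seed(seed)
  sort(sample.int(V, count))
}

#' Identity-by-state distance matrix
#'
#' PLINK-compatible dosage Hamming distance: for samples `i`, `j`,
#' `distance = mean(|dosage_i - dosage_j|) / 2` over sites called in both
#' (pairwise-complete), so 0 means identical genotypes and 1 opposite
#' homozygotes everywhere.
#'
#' @param genotypes `N x V` dosage matrix (0/1/2, `NA` missing), sample
#'   ids as rownames; see [hap_to_dosage()].
#' @return symmetric `N x N` matrix of `1 - IBS` values in `[0, 1]`; a
#'   pair with zero overlapping called sites gets `NA`.
#' @export
ibs_distance <- function(genotypes) {
  n <- nrow(genotypes)
  D <- matrix(0, n, n, dimnames = list(rownames(genotypes),
                                       rownames(genotypes)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- abs(genotypes[i, ] - genotypes[j, ])
      if (all(is.na(d))) {
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- mean(d, na.rm = TRUE) / 2
      }
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via [ape::nj()]); negative
#' branch lengths are clamped to 0 with the excess moved to the sister
#' branch, preserving path lengths through the parent node. Returns a
#' Newick string with branch lengths (6 significant digits).
#'
#' @param dist symmetric distance matrix, `n >= 3`, no missing entries.
#' @return Newick string (also returned invisibly as attribute `phylo`).
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop("nj_tree: need at least 3 taxa")
  if (anyNA(dist)) stop("nj_tree: distance matrix has missing entries")
  tr <- ape::nj(stats::as.dist(dist))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sisters)) {
      tr$edge.length[sisters[1L]] <- tr$edge.length[sisters[1L]] +
        tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length <- pmax(tr$edge.length, 0)
  nwk <- ape::write.tree(tr, digits = 6)
  structure(nwk, phylo = tr)
}
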