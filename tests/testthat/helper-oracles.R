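# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (loops, enumeration, literal formula transcription)
# and share no code with the package implementations they check.

# hap_matrix from a plain haplotype-by-site matrix (rows = haplotypes)
make_hap <- function(M, phased = TRUE, prefix = "s") {
  M <- as.matrix(M)
  stopifnot(nrow(M) %% 2 == 0)
  hap_matrix(M, sprintf("%s%02d", prefix, seq_len(nrow(M) / 2)), phased)
}

# variant table for V sites at given 1-based positions
make_vt <- function(pos, chrom = "1", ancestral = "ref",
                    effect = "other") {
  V <- length(pos)
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = sprintf("s%d", pos), ref = "A", alt = "C",
             effect_class = rep(effect, length.out = V),
             ancestral_state = rep(ancestral, length.out = V),
             stringsAsFactors = FALSE)
}

# popmap over consecutive samples: nf focal, nr reference, no outgroup
make_popmap <- function(nf, nr, no, prefix = "s") {
  n <- nf + nr + no
  data.frame(sample = sprintf("%s%02d", prefix, seq_len(n)),
             group = rep(c("cold", "warm", "outgroup"), c(nf, nr, no)),
             role = rep(c("focal", "reference", "outgroup"), c(nf, nr, no)),
             stringsAsFactors = FALSE)
}

# mean pairwise per-bp difference over all haplotype pairs (complete data)
oracle_pi <- function(H, L) {
  n <- nrow(H)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + sum(H[i, ] != H[j, ])
    np <- np + 1
  }
  tot / np / L
}

# literal transcription of the Hudson site formulas, ratio of sums
oracle_hudson <- function(p1, p2, n1, n2) {
  sN <- 0; sD <- 0
  for (i in seq_along(p1)) {
    N <- (p1[i] - p2[i])^2 -
      p1[i] * (1 - p1[i]) / (n1[i] - 1) -
      p2[i] * (1 - p2[i]) / (n2[i] - 1)
    D <- p1[i] * (1 - p2[i]) + p2[i] * (1 - p1[i])
    if (D > 0) { sN <- sN + N; sD <- sD + D }
  }
  sN / sD
}

# EHH at one extended interval by string enumeration: probability two
# random carrier haplotypes are identical over columns core..j
oracle_ehh_at <- function(H, carriers, cols) {
  keys <- apply(H[carriers, cols, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(keys)
  n <- length(carriers)
  sum(choose(cnt, 2)) / choose(n, 2)
}

# EHH12: all haplotypes, two most frequent extended classes pooled
oracle_ehh12_at <- function(H, rows, cols) {
  keys <- apply(H[rows, cols, drop = FALSE], 1, paste, collapse = "")
  cnt <- sort(as.integer(table(keys)), decreasing = TRUE)
  n <- length(rows)
  if (length(cnt) == 1) return(1)
  pooled <- c(cnt[1] + cnt[2], cnt[-(1:2)])
  sum(choose(pooled, 2)) / choose(n, 2)
}

# iHH12 by explicit curve + trapezoid, truncating at the cutoff
oracle_ihh12 <- function(H, pos, core, cutoff = 0.05) {
  n <- nrow(H)
  area_side <- function(idx) {
    x <- c(pos[core]); y <- c(1)
    for (j in idx) {
      cols <- if (j > core) core:j else j:core
      v <- oracle_ehh12_at(H, seq_len(n), cols)
      if (v < cutoff) break
      x <- c(x, pos[j]); y <- c(y, v)
    }
    if (length(x) < 2) return(0)
    sum(abs(diff(x)) * (y[-1] + y[-length(y)]) / 2)
  }
  right <- if (core < length(pos)) (core + 1):length(pos) else integer()
  left <- if (core > 1) (core - 1):1 else integer()
  area_side(right) + area_side(left)
}

# textbook 2x2 chi-square, sum (O - E)^2 / E
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# pairwise dosage IBS distance by explicit per-pair loop
oracle_ibs <- function(G) {
  n <- nrow(G)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) D[i, j] <- mean(abs(G[i, ] - G[j, ]), na.rm = TRUE) / 2
  }
  dimnames(D) <- list(rownames(G), rownames(G))
  D
}

# path-length (cophenetic) distances of a hand-specified 5-taxon tree
# with topology ((A,B),(C,D),E) and branch lengths bl (A,B,C,D,E,AB,CD)
additive_dist_5taxa <- function(bl) {
  nm <- c("A", "B", "C", "D", "E")
  D <- matrix(0, 5, 5, dimnames = list(nm, nm))
  path <- list(
    AB = bl[1] + bl[2],
    AC = bl[1] + bl[6] + bl[7] + bl[3],
    AD = bl[1] + bl[6] + bl[7] + bl[4],
    AE = bl[1] + bl[6] + bl[5],
    BC = bl[2] + bl[6] + bl[7] + bl[3],
    BD = bl[2] + bl[6] + bl[7] + bl[4],
    BE = bl[2] + bl[6] + bl[5],
    CD = bl[3] + bl[4],
    CE = bl[3] + bl[7] + bl[5],
    DE = bl[4] + bl[7] + bl[5])
  pairs <- combn(5, 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    D[i, j] <- D[j, i] <- path[[paste0(nm[i], nm[j])]]
  }
  D
}

# unordered leaf bipartitions induced by the internal edges of a phylo
tree_bipartitions <- function(tr) {
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  parts <- lapply(pp, function(idx) sort(labs[idx]))
  sapply(parts, paste, collapse = "|")
}

# global Hudson Fst of a sim_output via a single whole-contig window
global_fst <- function(sim) {
  w <- data.frame(chrom = "1", start = 0, end = sim$config$L, id = "all")
  hudson_fst(sim$hap, sim$variants, sim$popmap, w)$fst
}
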