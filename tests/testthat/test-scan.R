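# tiny hand-built inputs for the aggregation layer
agg_fixture <- function() {
  genes <- data.frame(chrom = "1",
                      start = c(0, 100, 200, 300, 400),
                      end = c(100, 200, 300, 400, 500),
                      id = paste0("g", 1:5), stringsAsFactors = FALSE)
  ws <- data.frame(id = paste0("w", 1:4), chrom = "1",
                   start = c(0, 50, 150, 350), end = c(50, 150, 250, 450),
                   n_sites = 5L,
                   fst = c(0.1, 0.4, 0.2, 0.05),
                   pi_focal = 1e-3, pi_reference = 2e-3,
                   log2_pi_ratio = c(1, 0.5, 2, Inf),
                   stringsAsFactors = FALSE)
  xp <- data.frame(chrom = "1", grid_pos = c(10, 120, 410),
                   clr = c(3, 7, 1), s_hat = 0.01, n_snps = 10L,
                   stringsAsFactors = FALSE)
  ihh <- data.frame(chrom = "1", pos = c(20, 130, 320, 460),
                    id = letters[1:4], ihh12 = 1, n_hap = 30,
                    z = c(0.5, 2.5, -1, 0.3), stringsAsFactors = FALSE)
  hka <- data.frame(id = paste0("g", 1:5), P = c(10L, 1L, 10L, 10L, 10L),
                    D = c(100L, 100L, 100L, 30L, 100L),
                    stringsAsFactors = FALSE)
  hka <- hka_test(hka, divergence_min = 60L)
  list(genes = genes, ws = ws, xp = xp, ihh = ihh, hka = hka)
}

test_that("gene aggregation takes per-component maxima over overlaps", {
  fx <- agg_fixture()
  gs <- aggregate_to_genes(fx$genes, fx$ws, fx$xp, fx$ihh, fx$hka)
  # g1 overlaps w1 (fst .1) and w2 (fst .4): max rule
  expect_equal(gs$fst[1], 0.4)
  # g2 overlaps w2 and w3: ratio max = 2; g4 gets the Inf sentinel
  expect_equal(gs$pi_ratio[2], 2)
  expect_identical(gs$pi_ratio[4], Inf)
  # grid points at 10 and 120 fall in g1/g2; 410 in g5
  expect_equal(gs$clr[1:2], c(3, 7))
  expect_equal(gs$clr[5], 1)
  expect_true(is.na(gs$clr[3]))          # no grid point in g3
  # max site z per gene; g5 has site at 460
  expect_equal(gs$ihh12_z[1], 0.5)
  expect_equal(gs$ihh12_z[4], -1)
  # hka: unusable unit g4 (D = 30) is missing
  expect_true(is.na(gs$hka[4]))
  expect_false(anyNA(gs$hka[c(1, 2, 3, 5)]))
})

test_that("outlier calling implements the joint top-q rule with tie handling", {
  set.seed(5)
  n <- 200
  g <- data.frame(gene = sprintf("g%03d", 1:n),
                  fst = runif(n), pi_ratio = runif(n), clr = runif(n),
                  ihh12_z = rnorm(n), hka = rnorm(n),
                  stringsAsFactors = FALSE)
  out <- call_outliers(g, q_pair = 0.05, q_site = 0.01)
  top10 <- function(x) rank(x) > n - 10
  expected <- top10(g$fst) & top10(g$pi_ratio)
  flagged <- out$outlier[out$method == "fst_pi"]
  expect_identical(flagged, unname(expected))
  expect_equal(sum(flagged), sum(expected))

  # single-statistic flagged count is q*n within one gene
  for (m in c("ihh12", "hka"))
    expect_lte(abs(sum(out$outlier[out$method == m]) - 0.01 * n), 1)

  # all-identical raw values: mid percentiles, no outliers
  g2 <- g; g2$ihh12_z <- 1
  out2 <- call_outliers(g2, q_site = 0.01)
  expect_equal(sum(out2$outlier[out2$method == "ihh12"]), 0)
})

test_that("flagged fractions track the nominal rate on random scores", {
  set.seed(6)
  n <- 500
  for (s in 1:10) {
    g <- data.frame(gene = as.character(1:n), fst = runif(n),
                    pi_ratio = runif(n), clr = runif(n),
                    ihh12_z = rnorm(n), hka = rnorm(n))
    out <- call_outliers(g, q_pair = 0.05, q_site = 0.01)
    expect_lte(abs(sum(out$outlier[out$method == "ihh12"]) - 5), 1)
    expect_lte(abs(sum(out$outlier[out$method == "hka"]) - 5), 1)
  }
})

test_that("method intersection applies the three-of-four rule", {
  sc <- data.frame(gene = rep(c("gA", "gB", "gC"), each = 4),
                   method = rep(c("fst_pi", "xpclr_pi", "ihh12", "hka"), 3),
                   stat1 = 1, stat2 = 1, percentile = 0.5,
                   outlier = c(TRUE, FALSE, TRUE, TRUE,     # gA: 3 methods
                               TRUE, TRUE, FALSE, FALSE,    # gB: 2 methods
                               TRUE, TRUE, TRUE, TRUE))     # gC: all 4
  cand <- intersect_methods(sc)
  expect_equal(cand$candidate, c(TRUE, FALSE, TRUE))
  expect_equal(cand$strict, c(FALSE, FALSE, TRUE))
  expect_equal(cand$methods[1], "fst_pi,hka,ihh12")
  expect_true(all(cand$gene[cand$strict] %in% cand$gene[cand$candidate]))
})

test_that("independent flags at nominal rates essentially never go strict", {
  set.seed(8)
  n <- 20000
  strict_total <- 0
  for (s in 1:10) {
    flags <- cbind(runif(n) < 0.05, runif(n) < 0.05,
                   runif(n) < 0.01, runif(n) < 0.01)
    strict_total <- strict_total + sum(rowSums(flags) == 4)
  }
  expect_lte(strict_total, 1)   # expectation is 10 * n * 2.5e-7 = 0.05
})

test_that("candidate sets are monotone in the outlier thresholds", {
  set.seed(9)
  n <- 300
  g <- data.frame(gene = as.character(1:n), fst = runif(n),
                  pi_ratio = runif(n), clr = runif(n),
                  ihh12_z = rnorm(n), hka = rnorm(n))
  cand_at <- function(qp, qs)
    with(intersect_methods(call_outliers(g, qp, qs)), gene[candidate])
  tight <- cand_at(0.05, 0.01)
  loose <- cand_at(0.15, 0.05)
  expect_true(all(tight %in% loose))

  # permuting gene labels permutes the output identically
  perm <- sample(n)
  g2 <- g[perm, ]
  out1 <- call_outliers(g, 0.05, 0.01)
  out2 <- call_outliers(g2, 0.05, 0.01)
  m1 <- out1[out1$method == "hka", ]
  m2 <- out2[out2$method == "hka", ]
  expect_identical(m2$outlier[match(m1$gene, m2$gene)], m1$outlier)
})

test_that("top variant selection ranks by delta-dAF within class with tie rules", {
  genes <- data.frame(chrom = "1", start = c(0, 100), end = c(100, 200),
                      id = c("gA", "gB"), stringsAsFactors = FALSE)
  cand <- data.frame(gene = c("gA", "gB"), methods = "", n_support = c(4L, 2L),
                     candidate = c(TRUE, FALSE), strict = c(TRUE, FALSE))
  daf <- data.frame(chrom = "1", pos = c(10L, 20L, 30L, 40L, 150L),
                    id = paste0("v", 1:5),
                    freq_focal = 1, freq_reference = 0,
                    delta_daf = c(0.9, 0.7, 0.95, 0.95, 0.99),
                    polarized = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                    effect_class = c("regulatory", "other", "missense",
                                     "missense", "regulatory"),
                    stringsAsFactors = FALSE)
  res <- top_variants(cand, genes, daf, min_methods = 4L)
  # gB is not strict: its 0.99 regulatory site must not win
  expect_equal(res$id[res$class == "regulatory" & res$leader], "v1")
  # exonic tie at 0.95: both reported, smaller coordinate leads
  ex <- res[res$class == "exonic", ]
  expect_equal(nrow(ex), 2L)
  expect_equal(ex$n_ties, c(2L, 2L))
  expect_equal(ex$id[ex$leader], "v3")
  # relaxing to >= 3 methods still excludes gB (2 supports)
  res3 <- top_variants(cand, genes, daf, min_methods = 3L)
  expect_equal(res3$id[res3$class == "regulatory" & res3$leader], "v1")
  # unpolarized sites are ineligible
  daf$polarized[1] <- FALSE
  res4 <- top_variants(cand, genes, daf, min_methods = 4L)
  expect_equal(nrow(res4[res4$class == "regulatory", ]), 0L)
})
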