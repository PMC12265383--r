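test_that("neutral simulation is deterministic and matches its configuration", {
  cfg <- sim_config(seed = 11, L = 1e6, theta_site = 1e-3, d_og = 0.01)
  s1 <- simulate_neutral(cfg)
  s2 <- simulate_neutral(cfg)
  expect_identical(s1$hap$H, s2$hap$H)
  expect_identical(s1$variants, s2$variants)

  # divergent-site count is Binomial(L, d_og); allow 3 sigma
  pig <- pop_rows(s1$hap, s1$popmap, role = c("focal", "reference"))
  og <- pop_rows(s1$hap, s1$popmap, role = "outgroup")
  pig_mono_ref <- colSums(s1$hap$H[pig, ] == 1L) == 0L
  og_fixed_alt <- colSums(s1$hap$H[og, ] == 0L) == 0L
  n_div <- sum(pig_mono_ref & og_fixed_alt)
  expect_lt(abs(n_div - 1e6 * 0.01), 3 * sqrt(1e6 * 0.01 * 0.99))

  # outgroup is monomorphic at every site
  expect_true(all(apply(s1$hap$H[og, ], 2, function(x) length(unique(x))) == 1))
})

test_that("theta_site = 0 leaves the pig panel monomorphic", {
  s <- simulate_neutral(sim_config(seed = 3, L = 2e5, theta_site = 0,
                                   d_og = 0.01))
  pig <- pop_rows(s$hap, s$popmap, role = c("focal", "reference"))
  expect_true(all(s$hap$H[pig, ] == 0L))
  expect_gt(ncol(s$hap$H), 0)   # divergent sites still emitted
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(L = 0), "zero-length")
  expect_error(sim_config(n_focal = 1), "sample counts")
  expect_error(sim_config(theta_site = 0.02, d_og = 0.01), "theta_site")
  expect_error(sim_config(sweep_on = TRUE, sweep_center = 1.95e6,
                          sweep_width = 2e5), "sweep interval")
})

test_that("background differentiation tracks the Balding-Nichols target", {
  fst <- sapply(1:2, function(s)
    global_fst(simulate_neutral(sim_config(seed = s, L = 5e5,
                                           fst_background = 0.05))))
  expect_lt(abs(mean(fst) - 0.05), 0.03)
})

test_that("sweep injection controls the focal sweep-site frequency exactly", {
  # f * 2 * n_focal integer: realized frequency equals f
  cfg <- sim_config(seed = 5, L = 5e5, sweep_on = TRUE, sweep_center = 2.5e5,
                    sweep_width = 1e5, sweep_fraction = 0.93, n_focal = 50)
  sim <- simulate_dataset(cfg)
  vt <- polarize(sim$hap, sim$variants, sim$popmap)
  i <- which(vt$id == "sweep_variant")
  ff <- allele_freq(sim$hap, vt, sim$popmap, "cold")
  fr <- allele_freq(sim$hap, vt, sim$popmap, "warm")
  expect_equal(ff$freq[i], 0.93)
  expect_equal(fr$freq[i], 0)
  expect_equal(sim$truth$f_realized, 0.93)

  # total replacement: zero focal diversity inside the interval, ddaf = 1
  cfg1 <- sim_config(seed = 5, L = 5e5, sweep_on = TRUE, sweep_center = 2.5e5,
                     sweep_width = 1e5, sweep_fraction = 1)
  s1 <- simulate_dataset(cfg1)
  vt1 <- polarize(s1$hap, s1$variants, s1$popmap)
  rf <- pop_rows(s1$hap, s1$popmap, role = "focal")
  inside <- which(vt1$pos - 1 >= 2e5 & vt1$pos - 1 < 3e5 &
                  vt1$id != "sweep_variant")
  expect_true(all(apply(s1$hap$H[rf, inside, drop = FALSE], 2,
                        function(x) length(unique(x))) == 1))
  dd <- delta_daf(allele_freq(s1$hap, vt1, s1$popmap, "cold"),
                  allele_freq(s1$hap, vt1, s1$popmap, "warm"))
  expect_equal(dd$delta_daf[which(vt1$id == "sweep_variant")], 1)

  # a sweep class below 2 haplotypes is refused
  expect_error(simulate_dataset(sim_config(seed = 5, sweep_on = TRUE,
                                           sweep_fraction = 0.02)),
               ">= 2 haplotypes")
})

test_that("identical configuration reproduces byte-identical VCF output", {
  cfg <- sim_config(seed = 9, L = 2e5, sweep_on = TRUE, sweep_center = 1e5,
                    sweep_width = 5e4, sweep_fraction = 0.5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_outputs(simulate_dataset(cfg), d1)
  write_outputs(simulate_dataset(cfg), d2)
  expect_identical(readLines(file.path(d1, "sim.vcf")),
                   readLines(file.path(d2, "sim.vcf")))
})

test_that("outputs round-trip through VCF and carry 1-based positions", {
  cfg <- sim_config(seed = 13, L = 1e5, sweep_on = TRUE, sweep_center = 5e4,
                    sweep_width = 2e4, sweep_fraction = 0.9)
  sim <- simulate_dataset(cfg)
  d <- withr::local_tempdir()
  files <- write_outputs(sim, d)
  back <- read_vcf(files$vcf, read_popmap(files$popmap))
  expect_identical(back$hap$H, sim$hap$H)
  expect_identical(back$variants$pos, sim$variants$pos)
  expect_identical(back$variants$effect_class, sim$variants$effect_class)

  truth <- jsonlite::read_json(files$truth, simplifyVector = TRUE)
  expect_equal(truth$interval, c(4e4, 6e4))
  expect_equal(truth$pos, 5e4 + 1)   # 0-based center -> 1-based POS

  # site at internal offset 0 is written as POS 1
  tiny <- list(hap = make_hap(matrix(c(0L, 1L), 2, 1)),
               variants = make_vt(1),
               popmap = data.frame(sample = "s01", group = "g",
                                   role = "focal"),
               genes = gene_tiles(10, 1),
               truth = list(sweep = FALSE),
               config = list(L = 10))
  f <- write_outputs(tiny, withr::local_tempdir())
  line <- grep("^1\t", readLines(f$vcf), value = TRUE)
  expect_match(line, "^1\t1\t")
})
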