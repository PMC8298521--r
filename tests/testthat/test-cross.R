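test_that("a chromosome of genetic length zero never recombines", {
  set.seed(1)
  for (i in 1:10) {
    hap <- simulate_meiosis(0, 12345)
    expect_equal(nrow(hap), 1)
    expect_equal(hap$start, 1)
    expect_equal(hap$end, 12345)
    expect_true(hap$origin %in% c("Gd", "Vx"))
  }
})

test_that("haplotype segments tile the chromosome with alternating origins", {
  set.seed(2)
  for (i in 1:50) {
    L <- sample(1e5:1e6, 1)
    hap <- simulate_meiosis(runif(1, 0, 300), L)
    expect_equal(hap$start[1], 1)
    expect_equal(hap$end[nrow(hap)], L)
    expect_true(all(hap$end >= hap$start))  # no zero-length segments
    if (nrow(hap) > 1) {
      expect_equal(hap$start[-1], hap$end[-nrow(hap)] + 1)
      expect_true(all(hap$origin[-1] != hap$origin[-nrow(hap)]))
    }
  }
})

test_that("marker discordance over many meioses follows the Haldane map", {
  set.seed(3)
  n <- 10000
  d <- 10  # cM
  disc <- 0
  for (i in seq_len(n)) {
    hap <- simulate_meiosis(d, 1e6)
    o <- origin_at(hap, pos = c(1, 1e6))
    disc <- disc + (o[1] != o[2])
  }
  p_hat <- disc / n
  p_exp <- haldane_r(d)  # 0.0906
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), 3 * se)
  # a marker compared with itself is never discordant
  hap <- simulate_meiosis(50, 1e6)
  expect_equal(origin_at(hap, pos = 5e5), origin_at(hap, pos = 5e5))
})

test_that("phenotype equals causal-locus origin under full penetrance", {
  cfg <- small_cross_config(seed = 4, n_progeny = 60)
  cross <- simulate_cross(cfg)
  expect_length(cross, 60)
  for (s in cross) {
    carrier <- origin_at(s$haplotype, "chr1", cfg$causal_pos) == "Gd"
    expect_equal(s$phenotype, if (carrier) "down" else "up")
  }
})

test_that("progeny phenotypes segregate 1:1", {
  cfg <- small_cross_config(seed = 5, n_progeny = 1000)
  frac_down <- mean(phenotypes(simulate_cross(cfg)) == "down")
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / 1000)
  expect_lt(abs(frac_down - 0.5), half_width)
})

test_that("the same seed reproduces the cross exactly", {
  cfg <- small_cross_config(seed = 6, n_progeny = 30, n_bulk = 10)
  expect_identical(simulate_cross(cfg), simulate_cross(cfg))
})

test_that("undetermined progeny are labelled and excluded from bulks", {
  cfg <- small_cross_config(seed = 7, n_progeny = 400,
                            undetermined_rate = 0.3)
  cross <- simulate_cross(cfg)
  ph <- phenotypes(cross)
  expect_gt(sum(ph == "undetermined"), 0)
  bulk <- make_bulk(cross, "down", 30)
  expect_true(all(phenotypes(bulk) == "down"))
})

test_that("bulk selection filters, truncates and reports shortfalls", {
  cfg <- small_cross_config(seed = 8, n_progeny = 100)
  cross <- simulate_cross(cfg)
  n_down <- sum(phenotypes(cross) == "down")
  bulk <- make_bulk(cross, "down", 40)
  expect_length(bulk, 40)
  expect_true(all(phenotypes(bulk) == "down"))
  # deterministic: first matching segregants in input order
  expect_equal(vapply(bulk, `[[`, "", "id"),
               vapply(cross[phenotypes(cross) == "down"], `[[`, "",
                      "id")[1:40])
  expect_error(make_bulk(cross, "down", n_down + 1),
               paste("only", n_down, "available"))
  expect_error(make_bulk(cross, "undetermined", 5), "cannot form a bulk")
  # bulk plus complement is the whole input
  all_down <- make_bulk(cross, "down", n_down)
  ids <- vapply(cross, `[[`, "", "id")
  expect_setequal(c(vapply(all_down, `[[`, "", "id"),
                    ids[phenotypes(cross) != "down"]), ids)
})

test_that("pooled depths have the configured mean coverage", {
  gen <- toy_genome("chr1", 1e7)
  markers <- even_marker_map(gen, 2000, 100)
  cfg <- cross_config(gen, markers, "chr1", 5e6, n_progeny = 60,
                      n_bulk = 48, seed = 9)
  bulk <- make_bulk(simulate_cross(cfg), "down", 24)
  depths <- simulate_pool_depths(bulk, markers, coverage = 50,
                                 error_rate = 0.01)
  total <- depths$gd_depth + depths$vx_depth
  se <- sqrt(50 / 2000)  # Poisson mean over 2000 markers
  expect_lt(abs(mean(total) - 50), 3 * se)
  expect_true(all(depths$gd_depth >= 0 & depths$vx_depth >= 0))
})

test_that("without sequencing error a pure-Gd marker yields no Vx reads", {
  gen <- toy_genome("chr1", 1e6)
  markers <- even_marker_map(gen, 10, 20)
  cfg <- cross_config(gen, markers, "chr1", 5e5, n_progeny = 80,
                      n_bulk = 20, seed = 10)
  bulk <- make_bulk(simulate_cross(cfg), "down", 20)
  depths <- simulate_pool_depths(bulk, markers, coverage = 60,
                                 error_rate = 0)
  geno <- genotype_matrix(bulk, markers)
  pure_gd <- colMeans(geno == "G") == 1
  expect_true(any(pure_gd))  # markers tightly linked to the causal locus
  expect_true(all(depths$vx_depth[pure_gd] == 0))
})

test_that("unlinked markers read ~50% Gd over replicate pools", {
  # law of total expectation over bulk composition: fresh cross per pool
  gen <- toy_genome(c("chr1", "chr2"), c(1e6, 1e6))
  markers <- even_marker_map(gen, c(5, 10), c(20, 20))
  set.seed(11)
  fracs <- replicate(200, {
    cfg <- cross_config(gen, markers, "chr1", 5e5, n_progeny = 100,
                        n_bulk = 24)
    bulk <- make_bulk(simulate_cross(cfg), "down", 24)
    d <- simulate_pool_depths(bulk, markers, coverage = 50,
                              error_rate = 0.01)
    unlinked <- d$chrom == "chr2"
    sum(d$gd_depth[unlinked]) / sum(d$gd_depth[unlinked] +
                                      d$vx_depth[unlinked])
  })
  expect_lt(abs(mean(fracs) - 0.5), 0.02)
})

test_that("Gd fraction at the causal marker reflects the error rate", {
  gen <- toy_genome("chr1", 1e6)
  markers <- marker_map(chrom = "chr1", pos_bp = 5e5, pos_cM = 25,
                        id = "causal", gd_allele = "A", vx_allele = "G")
  set.seed(12)
  e <- 0.05
  tot <- gd <- 0
  for (i in 1:100) {
    cfg <- cross_config(gen, markers, "chr1", 5e5, n_progeny = 80,
                        n_bulk = 20)
    bulk <- make_bulk(simulate_cross(cfg), "down", 20)
    d <- simulate_pool_depths(bulk, markers, coverage = 50, error_rate = e)
    gd <- gd + d$gd_depth; tot <- tot + d$gd_depth + d$vx_depth
  }
  expect_lt(abs(gd / tot - (1 - e)), 0.02)
})

test_that("recombinant fraction grows with genetic distance from the causal locus", {
  gen <- toy_genome("chr1", 1e6)
  # marker ladder at 0, 10, 20, 40 cM from the causal locus at the start
  markers <- marker_map(chrom = "chr1",
                        pos_bp = c(1000, 2e5, 4e5, 8e5),
                        pos_cM = c(0, 10, 20, 40),
                        id = c("m0", "m10", "m20", "m40"),
                        gd_allele = "A", vx_allele = "G")
  cfg <- cross_config(gen, markers, "chr1", 1000, n_progeny = 600,
                      n_bulk = 48, seed = 13)
  cross <- simulate_cross(cfg)
  geno <- genotype_matrix(cross, markers)
  causal <- geno[, "m0"]
  disc <- colMeans(geno != causal)
  expect_equal(unname(disc["m0"]), 0)
  expect_true(all(diff(disc[c("m0", "m10", "m20", "m40")]) > 0))
})

test_that("segregant and depth tables survive a TSV round trip", {
  cfg <- small_cross_config(seed = 14, n_progeny = 12, n_bulk = 4)
  cross <- simulate_cross(cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_segregant_table(cross, cfg$markers, tsv)
  back <- read_segregant_table(tsv)
  expect_equal(back$id, vapply(cross, `[[`, "", "id"))
  expect_equal(back$phenotype, phenotypes(cross))
  expect_equal(as.matrix(back[, cfg$markers$id]),
               genotype_matrix(cross, cfg$markers),
               ignore_attr = TRUE)

  d <- simulate_pool_depths(make_bulk(cross, "down", 4), cfg$markers,
                            seed = 15)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(d, tsv2)
  expect_equal(read_depth_table(tsv2), d)
})
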