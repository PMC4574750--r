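two_cat_tx <- function() {
  tx_tbl(c("m1", "m2", "r1"),
         c(strrep("ATGC", 100), strrep("GGCA", 100), strrep("GCGC", 200)),
         category = c("mRNA", "mRNA", "rRNA"))
}

test_that("composition fractions sum to one and report categories", {
  tx <- two_cat_tx()
  reads <- dplyr::bind_rows(rd("m1", 0:89, 27L), rd("r1", 0:9, 27L))
  comp <- composition(reads, tx)
  expect_equal(sum(comp$fraction), 1)
  expect_equal(comp$fraction[comp$category == "mRNA"], 0.9)
  # all-mRNA sample: fraction 1
  comp2 <- composition(rd("m1", 0:9, 27L), tx)
  expect_equal(comp2$fraction[comp2$category == "mRNA"], 1)
})

test_that("a 5% to 20% mRNA shift is a fourfold enrichment", {
  tx <- two_cat_tx()
  unt <- dplyr::bind_rows(rd("m1", 0:4, 27L, sample = "untreated"),
                          rd("r1", 0:94, 27L, sample = "untreated"))
  trt <- dplyr::bind_rows(rd("m1", 0:19, 27L, sample = "treated"),
                          rd("r1", 0:79, 27L, sample = "treated"))
  comp <- composition(dplyr::bind_rows(unt, trt), tx)
  expect_equal(enrichment_factor(comp, "treated", "untreated"), 4)
})

test_that("depletion thinning yields the closed-form composition", {
  truth <- make_transcriptome(n_transcripts = 10, seed = 71)
  sim <- simulate_reads(truth, geometry_preset("cr27"), n_reads = 20000,
                        seed = 72, rrna_fraction = 0.4)
  thinned <- simulate_depletion(sim$ribo, c(rRNA = 0.1, mRNA = 1),
                                seed = 73, transcripts = truth$transcripts,
                                sample = "treated")
  comp <- composition(dplyr::bind_rows(sim$ribo, thinned), truth$transcripts)
  r_surv <- sum(thinned$weight[thinned$transcript_id %in%
                                 truth$transcripts$transcript_id[
                                   truth$transcripts$category == "rRNA"]])
  m <- sum(sim$ribo$weight[!sim$ribo$transcript_id %in%
                             truth$transcripts$transcript_id[
                               truth$transcripts$category == "rRNA"]])
  expect_equal(comp$fraction[comp$sample == "treated" &
                               comp$category == "mRNA"],
               m / (m + r_surv))
  # survival 1 for everything is the identity
  same <- simulate_depletion(sim$ribo, 1, seed = 74)
  expect_equal(sum(same$weight), sum(sim$ribo$weight))
})

test_that("FPKM implements the unit definition and scale invariance", {
  tx <- tx_tbl("t1", strrep("A", 1000))
  # 10 reads on a 1 kb transcript out of a million mapped reads: FPKM 10.
  # Emulated with weights: one row of weight 10, the rest on a filler.
  tx2 <- dplyr::bind_rows(tx, tx_tbl("filler", strrep("A", 5000)))
  reads <- dplyr::bind_rows(rd("t1", 0L, 27L, weight = 10),
                            rd("filler", 0L, 27L, weight = 999990))
  fk <- fpkm(reads, tx2)
  expect_equal(fk$fpkm[fk$transcript_id == "t1"], 10)
  # doubling all counts leaves FPKM unchanged
  doubled <- reads
  doubled$weight <- doubled$weight * 2
  expect_equal(fpkm(doubled, tx2)$fpkm, fk$fpkm)
  # random store equals a brute-force recomputation
  set.seed(75)
  rnd <- rd("t1", sample(0:900, 50, TRUE), 27L,
            weight = sample(1:5, 50, TRUE))
  rnd <- dplyr::bind_rows(rnd, rd("filler", 0L, 27L, weight = 17))
  fk2 <- fpkm(rnd, tx2)
  total <- sum(rnd$weight)
  brute <- sum(rnd$weight[rnd$transcript_id == "t1"]) / 1 / (total / 1e6)
  expect_equal(fk2$fpkm[fk2$transcript_id == "t1"], brute)
  expect_error(fpkm(reads, tx_tbl("t1", "")), "zero-length")
})

test_that("fixed-slope R2 follows its definition, not a regression fit", {
  # exact proportionality: R2 = 1
  tab <- tibble::tibble(species = as.character(1:50),
                        count_a = 10:59, count_b = (10:59) * 2)
  r <- fixed_slope_r2(tab, totals = c(sum(tab$count_a), sum(tab$count_b)))
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  # exactly constant y has zero total variance: undefined, reported NA
  tab2 <- tibble::tibble(species = as.character(1:50),
                         count_a = 10:59, count_b = 30)
  r2 <- fixed_slope_r2(tab2, totals = c(sum(tab2$count_a), 50 * 30))
  expect_true(is.na(r2$r_squared))
  # near-constant y against varying x: non-positive R2
  tab2b <- tab2
  tab2b$count_b[1] <- 31
  r2b <- fixed_slope_r2(tab2b, totals = c(sum(tab2b$count_a),
                                          sum(tab2b$count_b)))
  expect_lte(r2b$r_squared, 0)
  # brute-force formula agreement on binomially split counts
  set.seed(76)
  n <- rnbinom(10000, size = 2, mu = 60) + 1
  y <- rbinom(10000, n, 0.6)
  x <- n - y
  tab3 <- tibble::tibble(species = as.character(1:10000),
                         count_a = x, count_b = y)
  totals <- c(sum(x), sum(y))
  r3 <- fixed_slope_r2(tab3, totals = totals)
  keep <- x > 5
  s <- totals[2] / totals[1]
  brute <- 1 - sum((y[keep] - s * x[keep])^2) /
    sum((y[keep] - mean(y[keep]))^2)
  expect_equal(r3$r_squared, brute, tolerance = 1e-12)
  # invariance under common rescaling of both samples
  tab4 <- tab3
  tab4$count_a <- tab4$count_a * 3
  tab4$count_b <- tab4$count_b * 3
  r4 <- fixed_slope_r2(tab4, min_count = 15, totals = totals * 3)
  r3b <- fixed_slope_r2(tab3, min_count = 5, totals = totals)
  expect_equal(r4$r_squared, r3b$r_squared, tolerance = 1e-12)
})

test_that("the chi-square envelope has the right threshold and geometry", {
  # the 95% chi-square(1) threshold is 3.841 to three decimals
  expect_equal(round(qchisq(0.95, 1), 3), 3.841)
  totals <- c(1e6, 2e6)
  env <- chi2_envelope(c(10, 100, 1000), totals)
  # a species exactly on the expected split lies inside
  tab <- tibble::tibble(species = "s", count_a = 100, count_b = 200)
  st <- species_envelope_test(tab, totals = totals)
  expect_equal(st$chi2, 0)
  expect_true(st$inside)
  # boundary consistency: the bounds themselves sit at the threshold
  y_up <- env$y_upper[env$x == 100]
  p_a <- totals[1] / sum(totals)
  n <- 100 + y_up
  chi_on_boundary <- (100 - p_a * n)^2 / (p_a * n) +
    (y_up - (1 - p_a) * n)^2 / ((1 - p_a) * n)
  expect_equal(chi_on_boundary, qchisq(0.95, 1), tolerance = 1e-8)
  expect_true(all(env$y_lower <= env$y_upper))
})

test_that("envelope coverage matches nominal under a no-depletion split", {
  set.seed(77)
  n_species <- 10000
  n <- rnbinom(n_species, size = 2, mu = 300) + 2
  p_b <- 0.55
  y <- rbinom(n_species, n, p_b)
  tab <- tibble::tibble(species = as.character(seq_len(n_species)),
                        count_a = n - y, count_b = y)
  st <- species_envelope_test(tab, totals = c(sum(tab$count_a),
                                              sum(tab$count_b)))
  inside <- mean(st$inside)
  expect_lt(abs(inside - 0.95), 3 * sqrt(0.95 * 0.05 / n_species))
})

test_that("GC content and total variation distance behave as defined", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content(c("GGGG", "ATAT")), c(1, 0))
  expect_equal(tv_distance(c(1, 1, 2), c(1, 1, 2)), 0)
  expect_equal(tv_distance(c(1, 0), c(0, 1)), 1)
})

test_that("property distributions flag GC-biased depletion and match on identity", {
  truth <- make_transcriptome(n_transcripts = 15, seed = 78, n_rrna = 0)
  sim <- simulate_reads(truth, geometry_preset("cr27"), n_reads = 15000,
                        seed = 79, rrna_fraction = 0)
  # identical stores: zero divergence for every property
  twin <- sim$ribo
  twin$sample <- "twin"
  res0 <- property_distributions(dplyr::bind_rows(sim$ribo, twin),
                                 truth$transcripts)
  expect_true(all(res0$divergence$tv_distance < 1e-12))
  # GC-dependent survival shifts the GC distribution detectably
  med <- stats::median(gc_content(sim$ribo$read_seq))
  biased <- simulate_depletion(
    sim$ribo,
    function(d) ifelse(gc_content(d$read_seq) > med, 0.3, 0.9),
    seed = 80, sample = "depleted"
  )
  res1 <- property_distributions(dplyr::bind_rows(sim$ribo, biased),
                                 truth$transcripts)
  gc_tv <- res1$divergence$tv_distance[res1$divergence$property == "gc"]
  expect_gt(gc_tv, 0.05)
})

test_that("external property tables join the distribution report", {
  truth <- make_transcriptome(n_transcripts = 5, seed = 81, n_rrna = 0)
  sim <- simulate_reads(truth, geometry_preset("cr27"), n_reads = 500,
                        seed = 82, rrna_fraction = 0)
  species <- unique(sim$ribo$read_seq)[1:50]
  tsv <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\tmfe\t%.2f", species, -runif(50, 1, 10)), tsv)
  props <- read_property_table(tsv)
  res <- suppressMessages(
    property_distributions(sim$ribo, truth$transcripts, properties = props)
  )
  expect_true("mfe" %in% res$distributions$property)
})
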