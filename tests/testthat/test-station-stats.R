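# ISIP share normalization and iron-stratified Pearson correlation.

toy_stations <- function(n = 10, chl = NULL, isip1 = NULL) {
  if (is.null(chl)) chl <- seq(0.1, 1, length.out = n)
  if (is.null(isip1)) isip1 <- seq_len(n)
  station_table(data.frame(
    station_id = sprintf("s%02d", seq_len(n)),
    chlorophyll = chl,
    iron = rep(0.2, n),
    isip1 = isip1,
    isip2a = rep(2, n),
    isip2b = rep(3, n),
    isip3 = rep(4, n),
    diatom_unigene_total = rep(1000, n)
  ))
}

test_that("ISIP shares close to 100% per station before unigene scaling", {
  shares <- isip_share(toy_stations())
  pct <- shares$isip1_share_pct + shares$isip2a_share_pct +
    shares$isip2b_share_pct + shares$isip3_share_pct
  expect_equal(pct, rep(100, nrow(shares)), tolerance = 1e-12)

  equal <- toy_stations(isip1 = rep(3, 10))
  eq_shares <- isip_share(equal)
  expect_equal(eq_shares$isip2b_share_pct, rep(25, 10), tolerance = 1e-12)

  solo <- toy_stations(n = 3)
  solo$isip2a <- solo$isip2b <- solo$isip3 <- rep(0, 3)
  solo_shares <- isip_share(solo)
  expect_equal(solo_shares$isip1_share_pct, rep(100, 3), tolerance = 1e-12)
  expect_equal(solo_shares$isip3_share_pct, rep(0, 3), tolerance = 1e-12)
})

test_that("stations with a zero four-gene sum are excluded with a warning", {
  tab <- toy_stations(n = 5)
  tab$isip1[2] <- tab$isip2a[2] <- tab$isip2b[2] <- tab$isip3[2] <- 0
  expect_warning(shares <- isip_share(tab), "s02")
  expect_identical(nrow(shares), 4L)
})

test_that("an exact linear relationship gives r = 1 and zero variance is flagged", {
  # build a table whose normalized isip1 share is exactly 2*chl + 1:
  # only isip1 expressed (share 100%), unigene total = 100 / (2*chl + 1)
  tab <- toy_stations()
  tab$isip2a <- tab$isip2b <- tab$isip3 <- rep(0, nrow(tab))
  tab$diatom_unigene_total <- 100 / (2 * tab$chlorophyll + 1)
  res <- stratified_pearson(tab, iron_bins(0.1, 0.3))
  expect_equal(res$r[1], 1, tolerance = 1e-9)

  flat <- toy_stations()
  flat$isip1 <- seq_len(nrow(flat))  # share of isip2a is along a constant pool
  flat$chlorophyll <- rep(0.5, nrow(flat))  # zero variance in x
  res2 <- stratified_pearson(flat, iron_bins(0.1, 0.3))
  expect_false(res2$computable[1])

  # y exactly affine in x through the construction of the generator
  gen <- make_station_table(seed = 9, bins = iron_bins(0.1, 0.3), rho = 1,
                            n_per_bin = 12)
  res3 <- stratified_pearson(gen, iron_bins(0.1, 0.3))
  expect_equal(res3$r[1], 1, tolerance = 1e-9)
})

test_that("per-bin Pearson r and p match a direct cor.test and mark small bins", {
  tab <- make_station_table(seed = 21, rho = c(0.5, 0.7, 0.3, 0))
  res <- stratified_pearson(tab)
  shares <- isip_share(tab)
  bin1 <- shares$iron >= 1.24 & shares$iron <= 1.39
  ct <- cor.test(shares$chlorophyll[bin1], shares$isip1_share_norm[bin1])
  expect_equal(res$r[1], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p[1], ct$p.value, tolerance = 1e-12)
  expect_identical(res$bin[nrow(res)], "pooled")
  expect_identical(res$n[nrow(res)], nrow(tab))

  tiny <- stratified_pearson(tab[1:2, ], iron_bins(1.24, 1.39))
  expect_false(any(tiny$computable))
})

test_that("stratified Pearson r is invariant to affine rescaling of x and y", {
  tab <- make_station_table(seed = 33, rho = c(0.6, 0.4, 0.2, 0))
  base <- stratified_pearson(tab)
  scaled <- tab
  scaled$chlorophyll <- 10 * scaled$chlorophyll + 3
  expect_equal(stratified_pearson(scaled)$r, base$r, tolerance = 1e-9)
  # positive rescaling of the normalized share via the unigene total
  scaled2 <- tab
  scaled2$diatom_unigene_total <- scaled2$diatom_unigene_total * 7
  expect_equal(stratified_pearson(scaled2)$r, base$r, tolerance = 1e-9)
})

test_that("normalization order does not affect within-bin correlation", {
  tab <- make_station_table(seed = 5, rho = c(0.7, 0.5, 0.3, 0.1))
  shares <- isip_share(tab)
  # unigene-first: scale the raw expressions, then take the percentage
  alt_pct <- 100 * (tab$isip1 / tab$diatom_unigene_total) /
    ((tab$isip1 + tab$isip2a + tab$isip2b + tab$isip3) /
       tab$diatom_unigene_total)
  alt_norm <- alt_pct / tab$diatom_unigene_total
  expect_equal(cor(shares$chlorophyll, shares$isip1_share_norm),
               cor(tab$chlorophyll, alt_norm), tolerance = 1e-12)
})

test_that("2^-ddCt relative expression behaves like the comparative-Ct method", {
  expect_identical(relative_expression_ddct(20, 20, 20, 20), 1)
  expect_identical(relative_expression_ddct(20, 15, 21, 15), 2)
  expect_equal(relative_expression_ddct(20, 15, 23.32, 15), 2^3.32,
               tolerance = 1e-12)
  expect_equal(relative_expression_ddct(20, 15, 23.32, 15), 10,
               tolerance = 2e-3)
  expect_error(relative_expression_ddct(NA, 1, 1, 1), "finite")
})

test_that("station tables reject duplicates and non-positive totals", {
  tab <- as.data.frame(toy_stations())
  tab$station_id[2] <- tab$station_id[1]
  expect_error(station_table(tab), "duplicate")
  tab2 <- as.data.frame(toy_stations())
  tab2$diatom_unigene_total[1] <- 0
  expect_error(station_table(tab2), "positive")
  expect_error(iron_bins(c(0, 0.4), c(0.5, 1)), "overlap")
})
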