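test_that("Fitch counts match hand cases and the brute-force oracle", {
  tree4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- c(a = "AAL", b = "AAL", c = "AVL", d = "ALL")
  ca <- clustered_alignment(aln, tree4, c("a", "b"), c("c", "d"))
  counts <- fitch_site_changes(ca)
  # site 1 constant -> 0 in both; two-leaf cluster differing -> 1
  expect_equal(counts$x1, c(0L, 0L, 0L))
  expect_equal(counts$x2, c(0L, 1L, 0L))
  # random trees up to 6 leaves against exhaustive ancestral labeling
  set.seed(8)
  aas <- c("A", "V", "L", "S")
  for (n in c(4, 5, 6)) {
    for (rep in 1:4) {
      tr <- ape::rtree(n, rooted = TRUE,
                       tip.label = paste0("t", seq_len(n)))
      for (site in 1:4) {
        st <- setNames(sample(aas, n, TRUE), tr$tip.label)
        got <- xenosig:::fitch_counts_tree(
          tr, matrix(st, 1, n, dimnames = list(NULL, tr$tip.label)))
        expect_equal(got, fitch_brute_force(tr, st))
      }
      # with a missing leaf
      st <- setNames(sample(c(aas, "-"), n, TRUE), tr$tip.label)
      got <- xenosig:::fitch_counts_tree(
        tr, matrix(st, 1, n, dimnames = list(NULL, tr$tip.label)))
      expect_equal(got, fitch_brute_force(tr, st))
    }
  }
})

test_that("heavily missing columns are masked", {
  tree <- ape::read.tree(text = "((a:1,b:1,c:1):1,(d:1,e:1):1);")
  aln <- c(a = "A-", b = "V-", c = "L-", d = "AA", e = "AV")
  ca <- clustered_alignment(aln, tree, c("a", "b", "c"), c("d", "e"))
  expect_message(counts <- fitch_site_changes(ca), "masked")
  expect_equal(counts$masked, c(FALSE, TRUE))
  expect_equal(counts$x1[1], 2L)
})

test_that("mixture log-likelihood collapses correctly at theta 0 and 1", {
  sim <- simulate_site_counts(80, 0.3, 1.2, 0.6, seed = 3)
  counts <- sim$counts
  l0 <- type1_loglik(counts, 0, 1.2, 0.6)
  l1 <- type1_loglik(counts, 1, 1.2, 0.6)
  lp0 <- sum(xenosig:::log_p0(counts$x1, counts$x2, 1, 1, 1.2, 0.6))
  lp1 <- sum(xenosig:::log_p1(counts$x1, 1, 1.2, 0.6) +
               xenosig:::log_p1(counts$x2, 1, 1.2, 0.6))
  expect_equal(l0, lp0)
  expect_equal(l1, lp1)
  # sitewise envelope: (1-t)p0 <= mix <= max(p0, p1) per site
  lp0_site <- xenosig:::log_p0(counts$x1, counts$x2, 1, 1, 1.2, 0.6)
  lp1_site <- xenosig:::log_p1(counts$x1, 1, 1.2, 0.6) +
    xenosig:::log_p1(counts$x2, 1, 1.2, 0.6)
  lm <- type1_loglik(counts, 0.4, 1.2, 0.6)
  expect_lte(lm, sum(pmax(lp0_site, lp1_site)))
  expect_gte(lm, max(l0 + 80 * log(0.6), l1 + 80 * log(0.4)))
})

test_that("closed-form marginals match numerical quadrature to 1e-8", {
  set.seed(10)
  for (rep in 1:20) {
    a <- runif(1, 0.4, 3); b <- runif(1, 0.2, 2)
    d1 <- runif(1, 0.5, 2); d2 <- runif(1, 0.5, 2)
    x1 <- sample(0:8, 1); x2 <- sample(0:8, 1)
    expect_equal(exp(xenosig:::log_p1(x1, d1, a, b)),
                 p1_quadrature(x1, d1, a, b), tolerance = 1e-8)
    expect_equal(exp(xenosig:::log_p0(x1, x2, d1, d2, a, b)),
                 p0_quadrature(x1, x2, d1, d2, a, b), tolerance = 1e-8)
  }
})

test_that("estimation recovers theta, orders posteriors and respects nesting", {
  sim <- simulate_site_counts(500, 0.4, 1, 0.5, seed = 42)
  fit <- estimate_type1(sim$counts)
  expect_gte(fit$lnL, fit$lnL_null)
  expect_gte(fit$lrt, 0)
  expect_true(fit$p > 0 && fit$p <= 1)
  expect_lt(abs(fit$theta - 0.4), 0.12)   # single-replicate slack
  expect_true(all(fit$qk >= 0 & fit$qk <= 1))
  expect_true(all(fit$critical_sites_095 %in% fit$critical_sites_070))
  # asymmetric sites score higher posteriors than balanced ones
  asym <- which(sim$counts$x1 >= 4 & sim$counts$x2 == 0)
  bal <- which(sim$counts$x1 == sim$counts$x2 & sim$counts$x1 > 0)
  expect_gt(min(fit$qk[asym]), max(fit$qk[bal]))
  # cluster relabeling leaves theta invariant
  swapped <- site_change_counts(sim$counts$x2, sim$counts$x1)
  fit_sw <- estimate_type1(swapped)
  expect_equal(fit_sw$theta, fit$theta, tolerance = 1e-4)
  expect_equal(fit_sw$lrt, fit$lrt, tolerance = 1e-3)
})

test_that("site posterior thresholds produce nested 1-based lists", {
  res <- list(qk = c(0.71, 0.96, 0.2, NA, 0.95))
  cs <- site_posteriors(res)
  expect_equal(cs$q070, c(1L, 2L, 5L))
  expect_equal(cs$q095, 2L)
  res2 <- list(qk = rep(0.5, 10))
  expect_equal(site_posteriors(res2)$q070, integer(0))
})

test_that("degenerate and boundary inputs are handled", {
  zero <- site_change_counts(rep(0L, 30), rep(0L, 30))
  expect_error(suppressWarnings(estimate_type1(zero)), "degenerate")
  sim0 <- simulate_site_counts(150, 0, 1, 0.5, seed = 77)
  fit0 <- estimate_type1(sim0$counts)
  if (fit0$theta < 1e-6) {
    expect_equal(fit0$lrt, 0)
    expect_equal(fit0$p, 1)
    expect_true(all(fit0$qk == 0))
  } else {
    expect_lt(fit0$theta, 0.2)
  }
})

test_that("the alignment simulator feeds the pipeline end to end", {
  sim <- simulate_clustered_alignment(8, 8, 150, 0.5, 1, 0.4, seed = 6)
  counts <- fitch_site_changes(sim$ca)
  expect_equal(counts$n_sites, 150)
  # parsimony counts track (approximately, from below) the planted ones
  expect_gte(cor(counts$x1, sim$counts$x1), 0.5)
  expect_true(all(counts$x1 >= 0))
  fit <- estimate_type1(counts)
  expect_gt(fit$theta, 0)
})
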