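test_that("RSCU normalization and exclusions follow the definition", {
  # equal usage of every synonymous codon -> all RSCU exactly 1
  gene <- paste(synonymous_codons(), collapse = "")
  r <- rscu(codon_counts(gene))
  expect_equal(unname(r$rscu), rep(1, 59))
  # Phe TTT=3, TTC=1 -> 1.5 / 0.5
  counts <- setNames(integer(64), codon_table()$codon)
  counts["TTT"] <- 3; counts["TTC"] <- 1
  r2 <- rscu(counts)
  expect_equal(unname(r2$rscu[c("TTT", "TTC")]), c(1.5, 0.5))
  expect_true(all(is.na(r2$rscu[setdiff(names(r2$rscu),
                                        c("TTT", "TTC"))])))
  # ATG, TGG and stops never appear in the table
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in%
                     names(r$rscu)))
})

test_that("RSCU matches a per-amino-acid recomputation on random counts", {
  set.seed(12)
  ct <- codon_table()
  syn <- synonymous_codons()
  for (rep in 1:5) {
    counts <- setNames(rpois(64, 8), ct$codon)
    r <- rscu(counts)
    for (aa in unique(names(syn))) {
      cods <- syn[names(syn) == aa]
      tot <- sum(counts[cods])
      for (cc in cods) {
        expected <- if (tot == 0) NA_real_
                    else counts[cc] / (tot / length(cods))
        expect_equal(unname(r$rscu[cc]), unname(expected))
      }
      # within-amino-acid mean RSCU is 1 whenever the amino acid occurs
      if (tot > 0) expect_equal(mean(r$rscu[cods]), 1)
    }
  }
})

test_that("chi-square comparison: zero under equality, df 41, hand summation", {
  mods <- demo_models()
  g <- generate_genome_with_transfers(60, mods$host, seed = 31)$genome
  ref <- genome_rscu(g)
  # a gene whose codon proportions equal the reference exactly
  res0 <- rscu_chi2_test(ref$codon_counts, ref)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)
  expect_equal(res0$df, 41)
  expect_equal(rscu_df(), 41)
  # toy gene vs toy reference: cell-by-cell oracle
  syn <- synonymous_codons()
  set.seed(4)
  gene_counts <- setNames(integer(64), codon_table()$codon)
  gene_counts[syn] <- rpois(59, 5)
  res <- rscu_chi2_test(gene_counts, ref)
  chi2_hand <- 0
  for (aa in unique(names(syn))) {
    cods <- syn[names(syn) == aa]
    prop <- ref$codon_counts[cods] / sum(ref$codon_counts[cods])
    expc <- sum(gene_counts[cods]) * prop
    use <- expc > 0
    chi2_hand <- chi2_hand +
      sum((gene_counts[cods][use] - expc[use])^2 / expc[use])
  }
  expect_equal(res$chi2, unname(chi2_hand))
  expect_equal(res$p, pchisq(res$chi2, 41, lower.tail = FALSE))
  # statistic depends on reference proportions only, not scale
  ref2 <- ref
  ref2$codon_counts <- ref$codon_counts * 7L
  expect_equal(rscu_chi2_test(gene_counts, ref2)$chi2, res$chi2)
})

test_that("CAI is the ratio of occurrence-means and hits its extremes", {
  # two-fold amino acid with reference RSCU {1.6, 0.4}: gene on the rare
  # codon scores 0.4 / 1.6
  ref_counts <- setNames(integer(64), codon_table()$codon)
  ref_counts["TTT"] <- 4; ref_counts["TTC"] <- 1
  ref <- rscu(ref_counts)
  gene <- setNames(integer(64), codon_table()$codon)
  gene["TTC"] <- 10
  res <- cai(gene, ref)
  expect_equal(res$cai, 0.25)
  expect_equal(res$cai_obs, 0.4)
  expect_equal(res$cai_max, 1.6)
  # occurrence-by-occurrence oracle on an arbitrary gene
  mods <- demo_models()
  g <- generate_genome_with_transfers(60, mods$host, seed = 41)$genome
  refg <- genome_rscu(g)
  gene2 <- codon_counts(g$nt_seq[5])
  res2 <- cai(gene2, refg)
  syn <- synonymous_codons()
  num <- den <- tot <- 0
  for (cc in syn) {
    k <- gene2[cc]
    if (k == 0) next
    aa <- names(syn)[syn == cc]
    mx <- max(refg$rscu[syn[names(syn) == aa]], na.rm = TRUE)
    rv <- refg$rscu[cc]; if (is.na(rv)) rv <- 0
    num <- num + k * rv; den <- den + k * mx; tot <- tot + k
  }
  expect_equal(res2$cai_obs, unname(num / tot))
  expect_equal(res2$cai_max, unname(den / tot))
  expect_equal(res2$cai, unname(num / den))
  expect_lte(res2$cai_obs, res2$cai_max)
  # unweighted genome-level CAImax alternative
  res3 <- cai(gene2, refg, max_weighting = "reference")
  aa_max <- tapply(refg$rscu[syn], names(syn), max, na.rm = TRUE)
  expect_equal(res3$cai_max, mean(aa_max))
})

test_that("CAI deviation rule flags beyond 1.5 dispersion units", {
  expect_true(cai_deviation_flag(0.66, 0.50, 0.10)$flag)    # 1.6 units
  expect_false(cai_deviation_flag(0.64, 0.50, 0.10)$flag)   # 1.4 units
  expect_true(cai_deviation_flag(0.34, 0.50, 0.10)$flag)    # two-sided
  expect_error(cai_deviation_flag(0.5, 0.5, 0), "zero")
  # flag rate at the threshold matches the empirical CAI distribution
  mods <- demo_models()
  g <- generate_genome_with_transfers(150, mods$host, seed = 51)$genome
  cs <- genome_cai_summary(g)
  flags <- abs(cs$cai - cs$mean) > 1.5 * cs$dispersion
  emp <- mean(flags)
  rate <- mean(vapply(cs$cai, function(v)
    cai_deviation_flag(v, cs$mean, cs$dispersion)$flag, logical(1)))
  expect_equal(rate, emp)
})

test_that("per-gene-mean reference pooling is available and differs", {
  mods <- demo_models()
  g <- generate_genome_with_transfers(50, mods$host, seed = 61)$genome
  pooled <- genome_rscu(g, pooling = "pooled")
  permean <- genome_rscu(g, pooling = "mean")
  expect_false(isTRUE(all.equal(pooled$rscu, permean$rscu)))
  # both keep the within-amino-acid mean-1 normalization for pooled counts
  syn <- synonymous_codons()
  for (aa in c("F", "K", "L")) {
    cods <- syn[names(syn) == aa]
    expect_equal(mean(pooled$rscu[cods]), 1)
  }
})
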