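test_that("GC by codon position matches hand counts", {
  p <- gc_profile("ATGGCC")
  expect_equal(c(p$gc1, p$gc2, p$gc3), c(50, 50, 100))
  expect_equal(p$gct, (50 + 50 + 100) / 3)
  expect_equal(p$counted_codons, 2)
  p0 <- gc_profile("AAAAAA")
  expect_equal(c(p0$gc1, p0$gc2, p0$gc3, p0$gct), c(0, 0, 0, 0))
  p1 <- gc_profile("GCGGCG")
  expect_equal(c(p1$gc1, p1$gc2, p1$gc3, p1$gct), c(100, 100, 100, 100))
  # ambiguous codons excluded entirely
  pn <- gc_profile("ATGNCCGGG")
  expect_equal(pn$counted_codons, 2)
  expect_equal(pn$gc3, 100)
  expect_error(gc_profile("NNN"), "countable")
})

test_that("gc profile merges under codon-preserving concatenation", {
  set.seed(3)
  for (i in 1:10) {
    a <- paste(sample(c("GCA", "ATT", "CGG", "TTT", "GGC"), 20, TRUE),
               collapse = "")
    b <- paste(sample(c("GCA", "ATT", "CGG", "TTT", "GGC"), 35, TRUE),
               collapse = "")
    pa <- gc_profile(a); pb <- gc_profile(b); pab <- gc_profile(paste0(a, b))
    w <- c(pa$counted_codons, pb$counted_codons)
    for (pos in c("gc1", "gc2", "gc3", "gct"))
      expect_equal(pab[[pos]],
                   sum(w * c(pa[[pos]], pb[[pos]])) / sum(w))
  }
})

test_that("genome GC summary equals an independent recomputation", {
  mods <- demo_models()
  g <- generate_genome_with_transfers(100, mods$host, seed = 9)$genome
  prof <- gc_profiles(g)
  sm <- genome_gc_summary(prof)
  # brute-force summation oracle
  for (pos in c("gc1", "gc2", "gc3", "gct")) {
    v <- prof[[pos]]
    expect_equal(unname(sm$mean[pos]), sum(v) / length(v))
    expect_equal(unname(sm$dispersion[pos]),
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  }
  expect_equal(sm$n_genes, 100)
  sem <- genome_gc_summary(prof, dispersion = "sem")
  expect_equal(sem$dispersion, sm$dispersion / sqrt(100))
  expect_error(genome_gc_summary(prof[1, , drop = FALSE]), "at least 2")
  # two genes with gct 40 and 60 -> mean 50; identical genes -> dispersion 0
  two <- data.frame(gc1 = c(40, 60), gc2 = c(40, 60), gc3 = c(40, 60),
                    gct = c(40, 60))
  expect_equal(unname(genome_gc_summary(two)$mean["gct"]), 50)
  same <- data.frame(gc1 = c(50, 50), gc2 = c(50, 50), gc3 = c(50, 50),
                     gct = c(50, 50))
  expect_equal(unname(genome_gc_summary(same)$dispersion["gct"]), 0)
})

test_that("the two-clause GC deviation rule flags as specified", {
  genome <- structure(list(
    mean = c(gc1 = 50, gc2 = 40, gc3 = 60, gct = 50),
    dispersion = c(gc1 = 2, gc2 = 2, gc3 = 4, gct = 3),
    n_genes = 100, dispersion_type = "sd"),
    class = "genome_gc_summary")
  mk <- function(g1, g3, gt)
    structure(list(gc1 = g1, gc2 = 40, gc3 = g3, gct = gt,
                   counted_codons = 100), class = "gc_profile")
  # total GC 2.5 dispersion units out -> clause 1
  f1 <- gc_deviation_flag(mk(50, 60, 50 + 2.5 * 3), genome)
  expect_true(f1$flag); expect_true(f1$clause_total)
  expect_false(f1$clause_13)
  # gc1 +1.0, gc3 +2.2 units, gct +1.0 -> clause 2 only
  f2 <- gc_deviation_flag(mk(50 + 1.0 * 2, 60 + 2.2 * 4, 50 + 1.0 * 3),
                          genome)
  expect_true(f2$flag); expect_true(f2$clause_13)
  expect_false(f2$clause_total)
  expect_equal(unname(f2$deviations[c("gc1", "gc3", "gct")]),
               c(1.0, 2.2, 1.0))
  # sub-threshold with opposite gc1/gc3 signs -> no flag
  f3 <- gc_deviation_flag(mk(50 - 1.5 * 2, 60 + 1.9 * 4, 50 + 1.0 * 3),
                          genome)
  expect_false(f3$flag)
  # zero dispersion reported and skipped
  genome$dispersion["gc1"] <- 0
  expect_warning(f4 <- gc_deviation_flag(mk(55, 60, 50), genome),
                 "zero genome dispersion")
  expect_true(is.na(f4$deviations["gc1"]))
})

test_that("single-model genomes flag few genes; shifted implants flag reliably", {
  mods <- demo_models()
  g <- generate_genome_with_transfers(200, mods$host, seed = 21)$genome
  prof <- gc_profiles(g)
  sm <- genome_gc_summary(prof)
  flags <- vapply(seq_len(nrow(prof)), function(i)
    gc_deviation_flag(as.list(prof[i, ]), sm)$flag, logical(1))
  expect_lte(mean(flags), 0.12)
  # implants with GC3 shifted >= 3 dispersion units are caught
  host <- make_codon_model(0.50, seed = 71)
  donor <- make_codon_model(0.70, seed = 72)
  mix <- generate_genome_with_transfers(200, host, donor,
                                        n_alien = 10, amelioration = 0,
                                        seed = 22)
  prof2 <- gc_profiles(mix$genome)
  sm2 <- genome_gc_summary(prof2)
  is_alien <- prof2$gene_id %in% mix$truth$alien_ids
  shift_units <- (mean(prof2$gc3[is_alien]) - sm2$mean["gc3"]) /
    sm2$dispersion["gc3"]
  expect_gte(abs(shift_units), 3)
  flags2 <- vapply(which(is_alien), function(i)
    gc_deviation_flag(as.list(prof2[i, ]), sm2)$flag, logical(1))
  expect_gte(mean(flags2), 0.9)
})
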