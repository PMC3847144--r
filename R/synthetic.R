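## Ground-truth generators: host/donor codon models with controlled GC3,
## synonymous-usage and 3:1 dinucleotide signatures; synthetic genomes
## with implanted transfers under a tunable amelioration degree; per-site
## substitution counts under the two-state divergence model; and strain
## trait tables with a planted enrichment.

## typical bacterial proteome amino-acid composition (normalized below)
AA_FREQS_DEFAULT <- c(
  A = 0.095, R = 0.055, N = 0.040, D = 0.054, C = 0.012,
  Q = 0.044, E = 0.058, G = 0.074, H = 0.022, I = 0.060,
  L = 0.105, K = 0.047, M = 0.027, F = 0.039, P = 0.044,
  S = 0.058, T = 0.054, W = 0.014, Y = 0.029, V = 0.070)

#' Build a codon model with a target GC3 and dinucleotide signature
#'
#' Within each amino acid, codon log-weights are a seeded synonymous
#' jitter plus a tilt toward G/C-ending codons; the tilt is solved so
#' that the expected third-position GC matches `gc3_target`, capped at
#' `bias_strength` in absolute value (an unreachable target is clamped
#' with a warning).  `bias_strength = 0` gives uniform synonymous usage.
#' The model also carries a doubly-centered 4x4 junction preference
#' matrix (scale `dinuc_bias`) that, during generation, tilts a codon's
#' third base conditional on the first base of the following codon —
#' giving the genome a controlled 3:1 dinucleotide signature.
#'
#' @param gc3_target Target third-position GC fraction in (0, 1).
#' @param bias_strength Cap on the GC3 tilt and switch for the
#'   synonymous jitter (default 2).
#' @param dinuc_bias Scale of the junction preference matrix
#'   (default 0.4).
#' @param seed Integer seed; the model is deterministic given it.
#' @param aa_freqs Amino-acid frequency vector (defaults to a typical
#'   bacterial composition).
#' @return An object of class `codon_model`.
#' @export
make_codon_model <- function(gc3_target, bias_strength = 2,
                             dinuc_bias = 0.4, seed = 1L,
                             aa_freqs = AA_FREQS_DEFAULT) {
  stopifnot(gc3_target > 0, gc3_target < 1, bias_strength >= 0)
  aa_freqs <- aa_freqs / sum(aa_freqs)
  ct <- codon_table()
  sense <- ct[ct$aa != "*", ]
  with_seed(seed, {
    jitter_sd <- 0.3 * min(1, bias_strength)
    jz <- setNames(rnorm(nrow(sense), 0, jitter_sd), sense$codon)
    j0 <- matrix(rnorm(16), 4, 4, dimnames = list(BASES, BASES))
    junction <- dinuc_bias *
      (j0 - rowMeans(j0) - rep(colMeans(j0), each = 4) + mean(j0))
  })
  is_gc3 <- substr(sense$codon, 3, 3) %in% c("G", "C")
  expected_gc3 <- function(t) {
    w <- exp(jz + t * is_gc3)
    gc3_aa <- tapply(seq_len(nrow(sense)), sense$aa, function(i)
      sum(w[i] * is_gc3[i]) / sum(w[i]))
    sum(aa_freqs[names(gc3_aa)] * gc3_aa) / sum(aa_freqs[names(gc3_aa)])
  }
  lo <- expected_gc3(-bias_strength)
  hi <- expected_gc3(bias_strength)
  if (gc3_target <= lo) {
    if (gc3_target < lo)
      warning("gc3_target ", gc3_target, " unreachable; clamped to ",
              round(lo, 3))
    t_hat <- -bias_strength
  } else if (gc3_target >= hi) {
    if (gc3_target > hi)
      warning("gc3_target ", gc3_target, " unreachable; clamped to ",
              round(hi, 3))
    t_hat <- bias_strength
  } else {
    t_hat <- uniroot(function(t) expected_gc3(t) - gc3_target,
                     c(-bias_strength, bias_strength), tol = 1e-9)$root
  }
  w <- exp(jz + t_hat * is_gc3)
  codon_probs <- setNames(numeric(nrow(sense)), sense$codon)
  for (aa in unique(sense$aa)) {
    i <- sense$aa == aa
    codon_probs[i] <- w[i] / sum(w[i])
  }
  ## conditional sampling tables: for each amino acid, codon probabilities
  ## given the first base of the succeeding codon (or none, last codon)
  cond <- list()
  for (aa in unique(sense$aa)) {
    cods <- sense$codon[sense$aa == aa]
    p <- codon_probs[cods]
    tab <- matrix(0, length(cods), 5,
                  dimnames = list(cods, c(BASES, "none")))
    tab[, "none"] <- p
    for (y in BASES) {
      py <- p * exp(junction[substr(cods, 3, 3), y])
      tab[, y] <- py / sum(py)
    }
    cond[[aa]] <- tab
  }
  structure(list(codon_probs = codon_probs, aa_freqs = aa_freqs,
                 junction = junction, cond = cond,
                 gc3_target = gc3_target, gc3_tilt = t_hat,
                 realized_gc3 = expected_gc3(t_hat),
                 bias_strength = bias_strength, dinuc_bias = dinuc_bias,
                 seed = seed),
            class = "codon_model")
}

## sample one gene's codons right-to-left so the third base can respond
## to the (already chosen) first base of the succeeding codon; `models`
## is a list of one model per codon position (mixture already resolved)
sample_codons <- function(aa_seq, models) {
  n <- length(aa_seq)
  out <- character(n)
  nxt <- "none"
  for (i in n:1) {
    tab <- models[[i]]$cond[[aa_seq[i]]]
    out[i] <- if (nrow(tab) == 1L) rownames(tab)
              else sample(rownames(tab), 1L, prob = tab[, nxt])
    nxt <- substr(out[i], 1, 1)
  }
  out
}

#' Generate a synthetic genome with implanted horizontal transfers
#'
#' Native genes are drawn codon-by-codon from the host model; alien
#' genes from the per-codon mixture `(1 - amelioration) * donor +
#' amelioration * host`, so amelioration 0 gives fully donor-like genes
#' and amelioration 1 genes indistinguishable from natives.  Every gene
#' is `ATG` + sense codons + `TAA`.
#'
#' @param n_genes Number of genes (default 200).
#' @param host,donor [make_codon_model()] objects (donor defaults to
#'   host, giving a transfer-free genome).
#' @param n_alien Number of implanted alien genes (default 0).
#' @param amelioration Mixture weight of the host model in alien genes,
#'   in `[0, 1]`.
#' @param length_dist Function drawing internal codon counts for `n`
#'   genes; default lognormal around 300 codons (sdlog 0.25), floored at
#'   100.
#' @param seed Integer seed; output is byte-reproducible given it.
#' @param genome_id Genome identifier for the generated [cds_set()].
#' @return A list with `genome` (a [cds_set()]) and `truth` (class
#'   `synthetic_truth`: `alien_ids`, `amelioration`, `seed`).
#' @export
generate_genome_with_transfers <- function(n_genes = 200, host,
                                           donor = NULL, n_alien = 0,
                                           amelioration = 0,
                                           length_dist = NULL,
                                           seed = 1L,
                                           genome_id = "synthetic") {
  stopifnot(n_alien <= n_genes, n_alien >= 0,
            amelioration >= 0, amelioration <= 1)
  if (is.null(donor)) donor <- host
  if (is.null(length_dist))
    length_dist <- function(n) pmax(100L, as.integer(round(
      rlnorm(n, meanlog = log(300), sdlog = 0.25))))
  aa_names <- names(host$aa_freqs)
  with_seed(seed, {
    lens <- length_dist(n_genes)
    alien_idx <- if (n_alien > 0) sort(sample.int(n_genes, n_alien))
                 else integer(0)
    seqs <- character(n_genes)
    for (g in seq_len(n_genes)) {
      aa_seq <- sample(aa_names, lens[g], replace = TRUE,
                       prob = host$aa_freqs)
      models <- if (g %in% alien_idx) {
        use_host <- runif(lens[g]) < amelioration
        lapply(use_host, function(h) if (h) host else donor)
      } else rep(list(host), lens[g])
      seqs[g] <- paste0("ATG", paste(sample_codons(aa_seq, models),
                                     collapse = ""), "TAA")
    }
  })
  ids <- sprintf("gene%04d", seq_len(n_genes))
  genome <- cds_set(ids, seqs, genome_id)
  truth <- structure(list(alien_ids = ids[alien_idx],
                          amelioration = amelioration, seed = seed),
                     class = "synthetic_truth")
  list(genome = genome, truth = truth)
}

#' Simulate per-site substitution counts under the two-state model
#'
#' For each of `L` sites, with probability `theta` the two clusters draw
#' independent rates `lambda_1, lambda_2 ~ Gamma(a, b)` (a diverged
#' site); otherwise they share a single rate.  Counts are Poisson with
#' mean `lambda_k * d_k`.
#'
#' @param L Number of sites.
#' @param theta True fraction of diverged sites, in `[0, 1]`.
#' @param a,b Gamma shape and rate of the site-rate distribution.
#' @param d1,d2 Cluster depths (default 1).
#' @param seed Integer seed.
#' @return A list with `counts` (a [site_change_counts()]) and
#'   `diverged` (logical truth labels per site).
#' @export
simulate_site_counts <- function(L, theta, a, b, d1 = 1, d2 = 1,
                                 seed = 1L) {
  stopifnot(L >= 1, theta >= 0, theta <= 1, a > 0, b > 0, d1 > 0, d2 > 0)
  with_seed(seed, {
    diverged <- runif(L) < theta
    lam_shared <- rgamma(L, shape = a, rate = b)
    lam1 <- ifelse(diverged, rgamma(L, shape = a, rate = b), lam_shared)
    lam2 <- ifelse(diverged, rgamma(L, shape = a, rate = b), lam_shared)
    x1 <- rpois(L, lam1 * d1)
    x2 <- rpois(L, lam2 * d2)
  })
  list(counts = site_change_counts(x1, x2, d1 = d1, d2 = d2),
       diverged = diverged)
}

## default categorical trait scheme for generated strain tables
TRAIT_SCHEME_DEFAULT <- list(
  habitat = c(host_associated = 0.30, aquatic = 0.20, terrestrial = 0.20,
              multiple = 0.20, specialized = 0.10),
  oxygen_requirement = c(aerobic = 0.40, anaerobic = 0.30,
                         facultative = 0.30),
  gram_stain = c(positive = 0.50, negative = 0.50),
  motility = c(yes = 0.60, no = 0.40))

#' Generate a strain trait table with a planted enrichment
#'
#' One designated category is sampled with the planted odds ratio among
#' family members; all other categories and all quantitative traits are
#' drawn at the same baseline in both groups.  Quantitative traits
#' emulate genome size (Mb), genomic GC% and optimal growth temperature.
#'
#' @param n_strains Total strains (default 1000).
#' @param n_family In-family strains (default 51).
#' @param categories Named list of category baseline probability vectors
#'   (defaults to a habitat / oxygen / Gram / motility scheme).
#' @param planted_or Odds ratio of the planted category among family
#'   members (default 1: null table).
#' @param planted_trait,planted_category Which category is planted
#'   (defaults to the first category of the first trait).
#' @param missingness Per-cell missingness probability (default 0.05).
#' @param seed Integer seed.
#' @return A list with `traits` (a `strain_traits` table) and `truth`
#'   (`trait`, `category`, `odds_ratio`, `seed`).
#' @export
generate_trait_table <- function(n_strains = 1000, n_family = 51,
                                 categories = TRAIT_SCHEME_DEFAULT,
                                 planted_or = 1,
                                 planted_trait = names(categories)[1],
                                 planted_category =
                                   names(categories[[1]])[1],
                                 missingness = 0.05, seed = 1L) {
  stopifnot(n_family <= n_strains, planted_or >= 1,
            missingness >= 0, missingness < 1)
  memb <- c(rep(TRUE, n_family), rep(FALSE, n_strains - n_family))
  with_seed(seed, {
    out <- data.frame(strain_id = sprintf("strain%05d", seq_len(n_strains)),
                      in_family = memb, stringsAsFactors = FALSE)
    for (tr in names(categories)) {
      base_p <- categories[[tr]] / sum(categories[[tr]])
      fam_p <- base_p
      if (tr == planted_trait && planted_category %in% names(base_p)) {
        p0 <- base_p[planted_category]
        p1 <- planted_or * p0 / (1 - p0 + planted_or * p0)
        fam_p[planted_category] <- p1
        others <- setdiff(names(base_p), planted_category)
        fam_p[others] <- base_p[others] * (1 - p1) / (1 - p0)
      }
      v <- character(n_strains)
      v[memb] <- sample(names(fam_p), sum(memb), replace = TRUE,
                        prob = fam_p)
      v[!memb] <- sample(names(base_p), sum(!memb), replace = TRUE,
                         prob = base_p)
      v[runif(n_strains) < missingness] <- NA
      out[[tr]] <- v
    }
    out$genome_size_mb <- round(pmax(0.5, rnorm(n_strains, 4, 1)), 2)
    out$gc_percent <- round(pmin(75, pmax(25, rnorm(n_strains, 50, 8))), 1)
    out$optimal_temp <- round(pmax(4, rnorm(n_strains, 35, 8)), 1)
    for (qc in c("genome_size_mb", "gc_percent", "optimal_temp"))
      out[[qc]][runif(n_strains) < missingness] <- NA
  })
  attr(out, "strain_col") <- "strain_id"
  attr(out, "membership_col") <- "in_family"
  class(out) <- c("strain_traits", "data.frame")
  list(traits = out,
       truth = list(trait = planted_trait, category = planted_category,
                    odds_ratio = planted_or, seed = seed))
}

#' Simulate a toy two-cluster alignment from site counts
#'
#' A thin, approximate wrapper over [simulate_site_counts()]: random
#' rooted binary subtrees are built for the two clusters, and for each
#' site the simulated number of substitutions is scattered as random
#' state changes on random edges of the cluster's subtree.  The realized
#' parsimony counts therefore approximate (and can fall below) the
#' simulated ones when changes collide; intended for qualitative
#' pipeline tests, not for calibration.
#'
#' @param n1,n2 Leaves in clusters 1 and 2.
#' @param L Number of sites.
#' @param theta,a,b Model parameters passed to [simulate_site_counts()].
#' @param seed Integer seed.
#' @return A list with `ca` (a [clustered_alignment()]), `counts` and
#'   `diverged` truth labels.
#' @export
simulate_clustered_alignment <- function(n1, n2, L, theta, a, b,
                                         seed = 1L) {
  sim <- simulate_site_counts(L, theta, a, b, seed = seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed + 1L, {
    make_clade <- function(n, prefix) {
      tr <- ape::rtree(n, rooted = TRUE,
                       tip.label = paste0(prefix, seq_len(n)))
      tr
    }
    t1 <- make_clade(n1, "c1_"); t2 <- make_clade(n2, "c2_")
    nwk <- paste0("(", sub(";$", "", ape::write.tree(t1)), ",",
                  sub(";$", "", ape::write.tree(t2)), ");")
    tree <- ape::read.tree(text = nwk)
    scatter <- function(tr, n_changes, root_state) {
      states <- setNames(rep(root_state, length(tr$tip.label)),
                         tr$tip.label)
      if (n_changes == 0 || length(tr$tip.label) < 2) return(states)
      for (j in seq_len(n_changes)) {
        e <- sample.int(nrow(tr$edge), 1L)
        nd <- tr$edge[e, 2]
        below <- if (nd <= length(tr$tip.label)) tr$tip.label[nd]
                 else ape::extract.clade(tr, nd)$tip.label
        states[below] <- sample(aas, 1L)
      }
      states
    }
    m <- matrix("", L, n1 + n2,
                dimnames = list(NULL, c(t1$tip.label, t2$tip.label)))
    for (s in seq_len(L)) {
      r <- sample(aas, 1L)
      m[s, t1$tip.label] <- scatter(t1, sim$counts$x1[s], r)
      m[s, t2$tip.label] <- scatter(t2, sim$counts$x2[s], r)
    }
  })
  aln <- setNames(apply(m, 2, paste, collapse = ""), colnames(m))
  ca <- clustered_alignment(aln, tree, t1$tip.label, t2$tip.label)
  list(ca = ca, counts = sim$counts, diverged = sim$diverged)
}
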