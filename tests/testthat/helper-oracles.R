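# Independent brute-force oracles and small fixture builders used across
# the suite.  Oracles deliberately avoid the package's own code paths.

# two-sided Fisher p by explicit hypergeometric enumeration over all
# tables with the observed margins (relative tolerance 1e-7)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kendall tau by O(n^2) concordant-minus-discordant pair counting
# (tie-free vectors)
kendall_pairs <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  unname(s / (n * (n - 1) / 2))
}

# minimum parsimony changes by exhaustive assignment of internal-node
# (and missing-tip) states on a rooted phylo tree
fitch_brute_force <- function(tree, tip_states) {
  miss_set <- c("-", "X", "?", ".", "*")
  st <- tip_states[tree$tip.label]
  n_tip <- length(tree$tip.label)
  alpha <- unique(st[!(st %in% miss_set | is.na(st))])
  if (length(alpha) <= 1) return(0L)
  free <- which(st %in% miss_set | is.na(st))          # tips free too
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  vary <- c(free, internal)
  grid <- expand.grid(rep(list(alpha), length(vary)),
                      stringsAsFactors = FALSE)
  best <- Inf
  fixed <- setNames(rep(NA_character_, n_tip + tree$Nnode),
                    seq_len(n_tip + tree$Nnode))
  fixed[seq_len(n_tip)] <- st
  for (r in seq_len(nrow(grid))) {
    lab <- fixed
    lab[vary] <- as.character(grid[r, ])
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  as.integer(best)
}

# negative-binomial / bivariate Poisson-gamma marginals by numerical
# integration over the gamma-distributed site rate
p1_quadrature <- function(x, d, a, b) {
  integrate(function(l) dpois(x, l * d) * dgamma(l, shape = a, rate = b),
            0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}
p0_quadrature <- function(x1, x2, d1, d2, a, b) {
  integrate(function(l) dpois(x1, l * d1) * dpois(x2, l * d2) *
              dgamma(l, shape = a, rate = b),
            0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

# a similarity_hits data.frame from parallel vectors
make_hits <- function(query, subject, bitscore, evalue = 1e-20,
                      alen = 100L, qlen = NULL, slen = NULL) {
  n <- length(query)
  out <- data.frame(query_id = query, subject_id = subject,
                    percent_identity = 90, alignment_length = alen,
                    mismatches = 5L, gap_opens = 0L, qstart = 1L,
                    qend = alen, sstart = 1L, send = alen,
                    evalue = evalue, bitscore = bitscore,
                    stringsAsFactors = FALSE)
  if (!is.null(qlen)) {
    out$query_length <- qlen
    out$subject_length <- slen
  }
  class(out) <- c("similarity_hits", "data.frame")
  out
}

# 4-gene, 20-codon set whose pooled 3:1 junctions cover all 16
# dinucleotides once with uniform positional base frequencies, so every
# relative abundance is exactly 1
uniform_junction_cds <- function() {
  firsts <- c("A", "C", "G", "T")
  mk_gene <- function(B, x, y) {
    f <- c(y, "A", "C", "G", "T")
    t <- c(B, B, B, B, x)
    paste(paste0(f, "C", t), collapse = "")
  }
  seqs <- mapply(mk_gene, B = c("A", "C", "G", "T"),
                 x = c("A", "C", "G", "T"), y = c("A", "C", "G", "T"))
  cds_set(paste0("u", 1:4), seqs, "uniform")
}

# deterministic small host/donor genome pair shared by screen tests
demo_models <- function() {
  list(host = make_codon_model(0.55, seed = 101),
       donor = make_codon_model(0.70, seed = 202))
}
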