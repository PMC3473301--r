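# Independent oracles and small fixture builders shared across test files.
# Each oracle re-derives the quantity by a different route than the package
# (direct counting, NIPALS recursion, balanced-design mean formulas,
# studentized-range quantiles) so agreement is informative.

# classical PLS1 via the NIPALS recursion; returns the coefficient vector
# at exactly A components (X deflated, y left alone)
nipals_pls1_beta <- function(X, y, A) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  W <- NULL; P <- NULL; q <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    w <- w / sqrt(sum(w^2))
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xc, t_) / tt
    q[a] <- sum(yc * t_) / tt
    Xc <- Xc - t_ %*% t(p_)
    W <- cbind(W, w); P <- cbind(P, p_)
  }
  as.vector(W %*% solve(crossprod(P, W), q))
}

# balanced two-fixed-one-random three-way ANOVA sums of squares from cell
# and marginal means (the textbook decomposition for one value per cell)
balanced_ss_oracle <- function(cells) {
  z <- cells$z
  A <- factor(cells$method); B <- factor(cells$representation)
  S <- factor(cells$species)
  m <- mean(z)
  mi <- tapply(z, A, mean); mj <- tapply(z, B, mean); mk <- tapply(z, S, mean)
  mij <- tapply(z, interaction(A, B), mean)
  na <- nlevels(A); nb <- nlevels(B); ns <- nlevels(S)
  ss_a <- nb * ns * sum((mi - m)^2)
  ss_b <- na * ns * sum((mj - m)^2)
  inter <- outer(mi - m, mj - m, `+`) + m  # additive prediction per (i,j)
  mij_mat <- matrix(mij, na, nb, dimnames = list(levels(A), levels(B)))
  ss_ab <- ns * sum((mij_mat - inter)^2)
  ss_s <- na * nb * sum((mk - m)^2)
  ss_tot <- sum((z - m)^2)
  c(method = ss_a, representation = ss_b, interaction = ss_ab,
    species = ss_s, residual = ss_tot - ss_a - ss_b - ss_ab - ss_s,
    total = ss_tot)
}

# direct-count oracle for a fixed-order chain with m/4 pseudo-counts spread
# by the empirical 0-order distribution (single-frame alphabets)
chain_oracle <- function(unit_seqs, B, k, pseudo_fraction = 0.25) {
  targets <- unlist(unit_seqs)
  p0 <- tabulate(targets + 1L, nbins = B) / length(targets)
  counts <- matrix(0, B^k, B)
  for (u in unit_seqs) {
    n <- length(u)
    for (t in (k + 1):n) {
      pre <- 0
      if (k > 0) for (o in 1:k) pre <- pre * B + u[t - k + o - 1L]
      counts[pre + 1L, u[t] + 1L] <- counts[pre + 1L, u[t] + 1L] + 1
    }
  }
  m <- sum(counts)
  pseudo <- (m * pseudo_fraction / nrow(counts)) *
    matrix(p0, nrow(counts), B, byrow = TRUE)
  aug <- counts + pseudo
  P <- aug / rowSums(aug)
  if (any(P == 0)) {
    P <- P + 1e-12
    P <- P / rowSums(P)
  }
  P
}

# deterministic toy ORF: start codon + given codons + stop
toy_orf <- function(codons) paste0("ATG", paste(codons, collapse = ""), "TAA")

# small two-class codon dataset with disjoint codon vocabularies
contrast_dataset <- function(n_per_class = 30L, len = 60L, seed = 1L) {
  set.seed(seed)
  pos <- replicate(n_per_class,
    paste(sample(c("GCT", "AAA", "GAT"), len, TRUE), collapse = ""))
  neg <- replicate(n_per_class,
    paste(sample(c("CCC", "GGG", "TTC"), len, TRUE), collapse = ""))
  data.frame(
    species_id = "toy", genome_id = "toy.g01",
    orf_id = sprintf("toy%03d", seq_len(2L * n_per_class)),
    seq = c(pos, neg),
    label = rep(c(1L, -1L), each = n_per_class),
    stringsAsFactors = FALSE
  )
}
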