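# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written as plain enumerations/arithmetic, separate from the
# package's own code paths.

# Spearman rho by explicit Pearson arithmetic on average ranks
oracleSpearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force average-rank score: loops over every (query, molecule) pair,
# ranks by descending rho with average ties, averages defined ranks, and
# orders by (average rank, -mean rho, id)
oracleAverageRank <- function(fc, query_ids) {
  ids <- rownames(fc)
  rks <- matrix(NA_real_, length(ids), length(query_ids),
                dimnames = list(ids, query_ids))
  rhs <- rks
  for (q in query_ids) {
    others <- setdiff(ids, q)
    rho <- vapply(others, function(m) oracleSpearman(fc[q, ], fc[m, ]),
                  numeric(1))
    rhs[others, q] <- rho
    rks[others, q] <- rank(-rho, ties.method = "average", na.last = "keep")
  }
  defined <- rowSums(!is.na(rks)) > 0
  avg <- rowMeans(rks, na.rm = TRUE)[defined]
  mrho <- rowMeans(rhs, na.rm = TRUE)[defined]
  keepIds <- ids[defined]
  ord <- order(avg, round(-mrho, 10), keepIds)
  data.frame(molecule_id = keepIds[ord], mean_rho = mrho[ord],
             average_rank = avg[ord], position = seq_along(ord),
             row.names = NULL)
}

# Exhaustive two-sided Fisher p over all tables with the observed margins,
# probabilities via log-binomial coefficients (independent of dhyper)
oracleFisherTwoSided <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0L, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  pObs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  sum(p[p <= pObs * (1 + 1e-7)])
}

# adjusted Rand index between two label vectors
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# small ScreenExperiment fixture for container tests
makeTinyScreen <- function(seed = 42) {
  simulateScreen(screenSimConfig(n_proteins = 30, n_lipids = 16,
                                 n_metabolites = 6, n_tag_species = 5,
                                 n_cl_species = 2, missing_rate = 0.05,
                                 seed = seed))
}
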