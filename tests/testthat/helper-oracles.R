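# Shared fixtures and independent oracles used across the suite.

# random topologically sorted pedigree: nf founders then offspring of
# earlier animals
random_pedigree <- function(n, nf = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sire <- dam <- integer(n)
  for (i in (nf + 1):n) {
    p <- sample.int(i - 1, 2)
    sire[i] <- p[1]; dam[i] <- p[2]
  }
  pedigree(sire, dam)
}

# dense multi-trait MME oracle: one mean per trait, animal effects with
# G0 (x) A covariance, residual partitioned per animal; returns EBV matrix
dense_mme_solve <- function(ped, Y, G0, R0, fit_mean = TRUE) {
  n <- nrow(ped); m <- ncol(Y)
  A <- relationship_matrix(ped)
  Ainv <- solve(A)
  G0i <- solve(G0)
  nb <- if (fit_mean) m else 0
  dim <- nb + n * m
  C <- matrix(0, dim, dim)
  rhs <- numeric(dim)
  for (i in seq_len(n)) {
    obs <- which(is.finite(Y[i, ]))
    if (length(obs) == 0) next
    W <- matrix(0, m, m)
    W[obs, obs] <- solve(R0[obs, obs, drop = FALSE])
    ui <- nb + (i - 1) * m + seq_len(m)
    yv <- ifelse(is.finite(Y[i, ]), Y[i, ], 0)
    C[ui, ui] <- C[ui, ui] + W
    rhs[ui] <- rhs[ui] + W %*% yv
    if (fit_mean) {
      C[seq_len(m), ui] <- C[seq_len(m), ui] + W
      C[ui, seq_len(m)] <- C[ui, seq_len(m)] + W
      C[seq_len(m), seq_len(m)] <- C[seq_len(m), seq_len(m)] + W
      rhs[seq_len(m)] <- rhs[seq_len(m)] + W %*% yv
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (Ainv[i, j] == 0) next
    ui <- nb + (i - 1) * m + seq_len(m)
    uj <- nb + (j - 1) * m + seq_len(m)
    C[ui, uj] <- C[ui, uj] + G0i * Ainv[i, j]
  }
  if (fit_mean) {
    # freeze means of traits without records
    for (t in seq_len(m)) if (all(!is.finite(Y[, t]))) {
      C[t, ] <- 0; C[, t] <- 0; C[t, t] <- 1; rhs[t] <- 0
    }
  }
  sol <- solve(C, rhs)
  list(b = if (fit_mean) sol[seq_len(m)] else numeric(m),
       u = t(matrix(sol[nb + seq_len(n * m)], m, n)))
}

# small trait set on a compact map, reused across tests
small_trait_set <- function(seed = 42, n_founders = 400, n_loci = 400,
                            n_qtl = 120) {
  set.seed(seed)
  map <- build_genetic_map(5, n_loci, 500)
  founders <- generate_founders(n_founders, map)
  list(map = map, founders = founders,
       ts = build_trait_set(map, founders, n_qtl = n_qtl))
}
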