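# Independent oracles. Each recomputes a quantity the package produces, by a
# deliberately different route: explicit strand-walk meiosis enumeration,
# a genotype-space one-locus recursion, plain power iteration, and a full
# nonlinear two-allele-modifier simulation.

# Brute-force meiosis: walk the chromosome locus by locus, tracking which
# parental strand the gamete is copying from; enumerate both starting strands
# and every crossover pattern. Returns the gamete distribution for parents
# given as allele vectors.
oracle_meiosis <- function(a1, a2, rec) {
  n <- length(a1)
  stopifnot(length(rec) == n - 1L)
  N <- 2L^n
  out <- numeric(N)
  patterns <- if (n == 1L) matrix(0L, 1L, 0L) else
    as.matrix(expand.grid(rep(list(0:1), n - 1L)))
  strands <- rbind(a1, a2)
  for (start in 1:2) {
    for (p in seq_len(nrow(patterns))) {
      pat <- patterns[p, ]
      cur <- start
      gam <- integer(n)
      gam[1L] <- strands[cur, 1L]
      for (t in seq_len(n - 1L)) {
        if (pat[t] == 1L) cur <- 3L - cur
        gam[t + 1L] <- strands[cur, t + 1L]
      }
      prob <- 0.5 * prod(ifelse(pat == 1L, rec, 1 - rec))
      idx <- sum(gam * 2L^((n - 1L):0L)) + 1L
      out[idx] <- out[idx] + prob
    }
  }
  out
}

# Genotype-space recursion for k = 1: tracks the three diploid genotypes per
# deme directly (no gamete tensor). Census at the gametic stage: input/output
# are allele-1 frequencies (p1, p2) in the two demes' gamete pools.
oracle_onelocus_step <- function(p, S, m, theta = 0, phi = 0) {
  w_geno <- function(deme) {
    # genotype order: 11, 10 (het), 00 in deme-1 allele counts
    dom <- if (deme == 1L) c(0, 1 - stats::plogis(theta), 1)
           else c(1, 1 - stats::plogis(-theta), 0)
    ph <- if (deme == 1L) phi else -phi
    l <- ifelse(dom %in% c(0, 1), dom, stats::plogis(stats::qlogis(dom) - ph))
    (1 - S)^l
  }
  m <- rep(m, length.out = 2L)
  geno <- lapply(1:2, function(d) {
    q <- p[d]
    c(q^2, 2 * q * (1 - q), (1 - q)^2)
  })
  out <- numeric(2L)
  wbar <- numeric(2L)
  for (d in 1:2) {
    e <- 3L - d
    g <- (1 - m[d]) * geno[[d]] + m[e] * geno[[e]]
    w <- w_geno(d)
    gw <- g * w
    wbar[d] <- sum(gw)
    out[d] <- (gw[1L] + gw[2L] / 2) / wbar[d]
  }
  list(p = out, w_bar = wbar)
}

# Plain left power iteration, independent of the package's implementation.
oracle_power_lambda <- function(A, iters = 20000L) {
  v <- rep(1 / nrow(A), nrow(A))
  lam <- NA_real_
  for (i in seq_len(iters)) {
    w <- as.vector(v %*% A)
    lam_new <- sum(w)
    w <- w / lam_new
    if (!is.na(lam) && abs(lam_new - lam) < 1e-13 && max(abs(w - v)) < 1e-10) break
    v <- w
    lam <- lam_new
  }
  lam_new
}

# Full nonlinear two-allele-modifier simulation over 2^(k+1) haplotypes per
# deme. Starts the modifier at frequency eps on every resident background,
# burns in to the dominant lineage shape (rescaling the carrier mass each
# generation to stay in the linear regime without distorting its
# distribution), then measures the per-generation growth factor.
oracle_modifier_growth <- function(eq, mod, eps = 1e-8, burn = 5000L,
                                   measure = 10L) {
  p <- eq$params
  k <- p$k
  hat <- migmod:::resolve_modifier(eq, mod)
  N <- 2L^k
  N2 <- 2L * N
  Gr <- migmod:::gamete_matrix(gamete_tensor(linkage_map(k, r = p$r, r_m = p$r_m)))
  Gm <- migmod:::gamete_matrix(gamete_tensor(
    linkage_map(k, r = hat$r_hat, r_m = hat$r_m_hat)))
  ft_res <- fitness_table(fitness_spec(S = p$S, theta = p$theta, phi = p$phi, k = k))
  ft_hat <- fitness_table(fitness_spec(S = hat$S_hat, theta = hat$theta_hat,
                                       phi = hat$phi_hat, k = k))
  carrier <- outer(0:(N2 - 1L) >= N, 0:(N2 - 1L) >= N, "|")
  ilo <- (0:(N2 - 1L)) %% N + 1L
  Wd <- lapply(1:2, function(d) {
    ifelse(carrier, ft_hat$W[[d]][ilo, ilo], ft_res$W[[d]][ilo, ilo])
  })
  mm <- lapply(1:2, function(d) ifelse(carrier, hat$m_hat[d], p$m[d]))
  x <- lapply(1:2, function(d) {
    c(eq$x[[d]] * (1 - eps), eq$x[[d]] * eps)
  })
  stepfun <- function(x) {
    P <- lapply(1:2, function(d) outer(x[[d]], x[[d]]))
    lapply(1:2, function(d) {
      e <- 3L - d
      M <- ((1 - mm[[d]]) * P[[d]] + mm[[e]] * P[[e]]) * Wd[[d]]
      y <- as.vector(Gm %*% as.vector(M * carrier)) +
        as.vector(Gr %*% as.vector(M * !carrier))
      y / sum(y)
    })
  }
  qfreq <- function(x) sum(x[[1L]][(N + 1L):N2]) + sum(x[[2L]][(N + 1L):N2])
  renorm <- function(x, target) {
    s <- target / qfreq(x)
    for (d in 1:2) {
      q <- sum(x[[d]][(N + 1L):N2])
      x[[d]][(N + 1L):N2] <- x[[d]][(N + 1L):N2] * s
      x[[d]][1:N] <- x[[d]][1:N] * ((1 - s * q) / (1 - q))
    }
    x
  }
  for (t in seq_len(burn)) x <- renorm(stepfun(x), 2 * eps)
  g <- NA_real_
  for (t in seq_len(measure)) {
    q0 <- qfreq(x)
    x <- stepfun(x)
    g <- qfreq(x) / q0
    x <- renorm(x, 2 * eps)
  }
  g
}

# default resident equilibria reused across tests (memoised by the package)
baseline_eq <- function(k, ...) {
  solve_equilibrium(k = k, S = 0.1, m = 0.05, r = 0.5, r_m = 0, ...)
}
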