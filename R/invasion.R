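#' Specify a modifier allele
#'
#' A modifier is a rare mutant allele at the map's position-1 locus that
#' changes one (or more) parameters of the genetic architecture for its
#' carriers. Hat parameters left `NULL` default to the resident values, so an
#' empty spec is the null (neutral) modifier. Hat values are the parameters
#' expressed by modifier heterozygotes: the recombination modifier is
#' dominant (carrier meiosis uses the mutant recombination vector
#' throughout), and the fitness/dispersal modifiers are co-dominant — only
#' heterozygous carriers matter during invasion, since matings between two
#' carriers are rarer still.
#'
#' @param S_hat Mutant total cost of maladaptation.
#' @param r_hat Mutant recombination between adjacent local-adaptation loci
#'   (scalar or length `k - 1`).
#' @param r_m_hat Mutant recombination between the modifier and locus 1.
#' @param theta_hat Mutant dominance parameter(s) for the loci in
#'   `affected_loci` (scalar, or one value per affected locus).
#' @param affected_loci Which local-adaptation loci the dominance modifier
#'   acts on (default: all loci).
#' @param phi_hat Mutant epistasis parameter.
#' @param m_hat Mutant (carrier) migration rate(s), scalar or per-deme pair.
#' @return An object of class `modifier_spec`.
#' @examples
#' modifier_spec()                        # null modifier
#' modifier_spec(phi_hat = 10)            # extreme epistasis modifier
#' modifier_spec(r_hat = 0, r_m_hat = 0)  # inversion-like modifier
#' @export
modifier_spec <- function(S_hat = NULL, r_hat = NULL, r_m_hat = NULL,
                          theta_hat = NULL, affected_loci = NULL,
                          phi_hat = NULL, m_hat = NULL) {
  if (!is.null(r_hat)) r_hat <- check_rec(r_hat, "r_hat")
  if (!is.null(r_m_hat)) r_m_hat <- check_rec(r_m_hat, "r_m_hat")
  if (!is.null(m_hat)) m_hat <- check_migration(m_hat)
  if (!is.null(affected_loci) && is.null(theta_hat)) {
    stop("`affected_loci` needs a `theta_hat`", call. = FALSE)
  }
  structure(
    list(S_hat = S_hat, r_hat = r_hat, r_m_hat = r_m_hat,
         theta_hat = theta_hat, affected_loci = affected_loci,
         phi_hat = phi_hat, m_hat = m_hat),
    class = "modifier_spec"
  )
}

modifier_type <- function(mod) {
  set <- c(
    S = !is.null(mod$S_hat),
    recombination = !is.null(mod$r_hat) || !is.null(mod$r_m_hat),
    dominance = !is.null(mod$theta_hat),
    epistasis = !is.null(mod$phi_hat),
    dispersal = !is.null(mod$m_hat)
  )
  if (!any(set)) "null" else paste(names(set)[set], collapse = "+")
}

#' @export
print.modifier_spec <- function(x, ...) {
  cat("<modifier_spec> type:", modifier_type(x), "\n")
  for (f in names(x)) {
    if (!is.null(x[[f]])) {
      cat("  ", f, " = ", paste(format(x[[f]]), collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

# resolve hat parameters against the resident values stored in an equilibrium
resolve_modifier <- function(eq, mod) {
  p <- eq$params
  k <- p$k
  theta_hat <- p$theta
  if (!is.null(mod$theta_hat)) {
    loci <- if (is.null(mod$affected_loci)) seq_len(k) else as.integer(mod$affected_loci)
    if (any(loci < 1L) || any(loci > k)) {
      stop("`affected_loci` must be in 1..k", call. = FALSE)
    }
    theta_hat[loci] <- mod$theta_hat
  }
  r_hat <- if (is.null(mod$r_hat)) p$r else {
    rh <- mod$r_hat
    if (length(rh) == 1L && k > 2L) rh <- rep(rh, k - 1L)
    if (k == 1L) numeric(0) else rh
  }
  if (k > 1L && length(r_hat) != k - 1L) {
    stop("`r_hat` must have length 1 or k - 1", call. = FALSE)
  }
  list(
    S_hat = if (is.null(mod$S_hat)) p$S else mod$S_hat,
    r_m_hat = if (is.null(mod$r_m_hat)) p$r_m else mod$r_m_hat,
    r_hat = r_hat,
    theta_hat = theta_hat,
    phi_hat = if (is.null(mod$phi_hat)) p$phi else mod$phi_hat,
    m_hat = if (is.null(mod$m_hat)) p$m else mod$m_hat
  )
}

# Reproduction block for one deme: carrier states (mu, rho) -> carrier
# offspring states, before migration. Rows and columns are indexed
# s = mu * 2^k + rho + 1 (mu = carrier's modifier-bearing haplotype's local
# bits, rho = its resident partner haplotype). Entry [i, j] is the expected
# number of modifier-bearing gametes of local type j_mu produced by carrier i
# (meiosis under the mutant recombination vector, modifier bit tracked
# explicitly) times the probability of fusing with a resident gamete j_rho,
# times 2 successful gametes per adult at demographic equilibrium.
build_reproduction_block <- function(v, gt_mut, k) {
  N <- 2L^k
  stopifnot(gt_mut$n_loci == k + 1L, length(v) == N)
  # G[j_full, i_mu_full, i_r_full]: modifier bit is the MSB, so
  # modifier-bearing haplotypes occupy indices (N+1):(2N)
  Gsub <- gt_mut$G[(N + 1L):(2L * N), (N + 1L):(2L * N), 1:N, drop = FALSE]
  # -> [i_mu, i_r, j_mu], rows (i_mu, i_r) with i_r fastest
  M <- matrix(aperm(Gsub, c(3L, 2L, 1L)), nrow = N * N)
  R <- 2 * M[, rep(seq_len(N), each = N), drop = FALSE]
  R * rep(rep(v, times = N), each = N * N)
}

# Block migration matrix over both demes' carrier states at the mutant rates
build_dispersal_block <- function(R1, R2, m_hat) {
  rbind(
    cbind(R1 * (1 - m_hat[1L]), R1 * m_hat[1L]),
    cbind(R2 * m_hat[2L], R2 * (1 - m_hat[2L]))
  )
}

# Relative-fitness vector over carrier states: mutant-parameterised fitness
# of the (mu, rho) diploid in the destination deme, normalised by the
# resident mean fitness of that deme (the post-selection normaliser of the
# resident recursion, recorded at the converged equilibrium).
build_selection_vector <- function(eq, hat) {
  k <- eq$params$k
  spec_hat <- fitness_spec(S = hat$S_hat, theta = hat$theta_hat,
                           phi = hat$phi_hat, k = k)
  ft_hat <- fitness_table(spec_hat)
  if (any(eq$w_bar <= 0)) stop("invalid resident mean fitness", call. = FALSE)
  # state order within a deme: (mu, rho) with rho fastest; W is symmetric
  c(as.vector(t(ft_hat$W[[1L]])) / eq$w_bar[1L],
    as.vector(t(ft_hat$W[[2L]])) / eq$w_bar[2L])
}

#' Dominant eigenvalue of a non-negative matrix
#'
#' The invasion matrix is non-negative, so its spectral radius is attained at
#' a real (Perron) eigenvalue. `method = "eigen"` uses a full dense
#' eigendecomposition; `method = "power"` uses left power iteration
#' (`v <- v A`), which is faster for the largest systems.
#'
#' @param A Square non-negative matrix.
#' @param method `"eigen"` (default) or `"power"`.
#' @param tol Convergence tolerance for power iteration.
#' @param max_iter Iteration cap for power iteration.
#' @return The dominant eigenvalue (a real scalar).
#' @export
dominant_eigenvalue <- function(A, method = c("eigen", "power"),
                                tol = 1e-13, max_iter = 100000L) {
  method <- match.arg(method)
  if (method == "eigen") {
    ev <- eigen(A, only.values = TRUE)$values
    lead <- ev[which.max(Mod(ev))]
    if (abs(Im(lead)) > 1e-8 * max(1, abs(Re(lead)))) {
      stop("dominant eigenvalue is not real", call. = FALSE)
    }
    return(Re(lead))
  }
  n <- nrow(A)
  v <- rep(1 / n, n)
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- as.vector(v %*% A)
    lam_new <- sum(w)
    if (lam_new <= 0) stop("power iteration collapsed", call. = FALSE)
    w <- w / lam_new
    if (!is.na(lam) && abs(lam_new - lam) < tol * max(1, lam_new) &&
        max(abs(w - v)) < sqrt(tol)) {
      return(lam_new)
    }
    v <- w
    lam <- lam_new
  }
  warning("power iteration hit max_iter; returning last estimate", call. = FALSE)
  lam
}

#' Theoretical maximum strength of selection on a modifier
#'
#' Upper bound on the invasion rate of any modifier that cannot push absolute
#' fitness above 1: the growth rate of a hypothetical load-free carrier
#' lineage, whose relative fitness in deme d is `1 / w_bar_d`, coupled by the
#' resident migration rates. It is the dominant eigenvalue, minus 1, of the
#' 2x2 matrix `[(1 - m1) c1, m1 c2; m2 c1, (1 - m2) c2]` with
#' `c_d = 1 / w_bar_d`. With symmetric demes it reduces to `L / (1 - L)`.
#'
#' @param eq A converged [solve_equilibrium()] result.
#' @return The bound on the selection coefficient (lambda_max - 1).
#' @export
theoretical_max <- function(eq) {
  stopifnot(inherits(eq, "mig_equilibrium"))
  m <- eq$params$m
  cc <- 1 / eq$w_bar
  B <- matrix(c((1 - m[1L]) * cc[1L], m[2L] * cc[1L],
                m[1L] * cc[2L], (1 - m[2L]) * cc[2L]), 2L, 2L)
  dominant_eigenvalue(B) - 1
}

#' Invasion analysis of a rare modifier allele
#'
#' Linearises the dynamics of a rare modifier lineage around a converged
#' resident equilibrium and measures its long-run growth rate. Carrier states
#' are (deme, modifier-bearing haplotype's local alleles, resident partner
#' haplotype), giving a `2^(2k+1)`-dimensional system. The invasion matrix is
#' assembled in three stages: per-deme reproduction blocks (meiosis at the
#' mutant recombination vector and syngamy with resident gametes), carrier
#' migration at the mutant rates, and relative viability under the mutant
#' fitness parameters, normalised by resident mean fitness. The modifier's
#' selection coefficient is the dominant eigenvalue minus 1; a null modifier
#' gives exactly 1 (neutrality).
#'
#' @param eq A converged [solve_equilibrium()] result.
#' @param mod A [modifier_spec()] (default: null modifier).
#' @param method Eigenvalue method, see [dominant_eigenvalue()].
#' @param keep_matrix Keep the invasion matrix in the result (it is
#'   `2^(2k+1)` square; 32 MB at k = 5).
#' @return An object of class `mig_invasion` with `lambda`, `selection`
#'   (`lambda - 1`), `selection_max` (the [theoretical_max()] bound), the
#'   resolved hat parameters, and references to `mod` and `eq`.
#' @examples
#' eq <- solve_equilibrium(k = 2, S = 0.1, m = 0.05)
#' inv <- invasion_analysis(eq, modifier_spec(phi_hat = 10))
#' glance(inv)
#' @export
invasion_analysis <- function(eq, mod = modifier_spec(),
                              method = c("eigen", "power"),
                              keep_matrix = FALSE) {
  stopifnot(inherits(eq, "mig_equilibrium"), inherits(mod, "modifier_spec"))
  if (!eq$converged) {
    stop("resident equilibrium has not converged; rerun with more generations",
         call. = FALSE)
  }
  method <- match.arg(method)
  A <- invasion_matrix(eq, mod)
  lambda <- dominant_eigenvalue(A, method = method)
  out <- structure(
    list(
      lambda = lambda,
      selection = lambda - 1,
      selection_max = theoretical_max(eq),
      type = modifier_type(mod),
      hat = resolve_modifier(eq, mod),
      mod = mod,
      eq = eq,
      A = if (keep_matrix) A else NULL
    ),
    class = "mig_invasion"
  )
  out
}

#' Assemble the invasion matrix of a modifier
#'
#' @inheritParams invasion_analysis
#' @return The `2^(2k+1)` square non-negative matrix `A` whose dominant
#'   eigenvalue is the modifier's growth rate; iteration is by left
#'   multiplication (`nu <- nu A`).
#' @export
invasion_matrix <- function(eq, mod = modifier_spec()) {
  stopifnot(inherits(eq, "mig_equilibrium"), inherits(mod, "modifier_spec"))
  k <- eq$params$k
  hat <- resolve_modifier(eq, mod)
  map_mut <- linkage_map(k = k, r = hat$r_hat, r_m = hat$r_m_hat)
  gt_mut <- gamete_tensor(map_mut)
  R1 <- build_reproduction_block(eq$x[[1L]], gt_mut, k)
  R2 <- build_reproduction_block(eq$x[[2L]], gt_mut, k)
  D <- build_dispersal_block(R1, R2, hat$m_hat)
  f <- build_selection_vector(eq, hat)
  # A[i, j] = D[i, j] * f[j]: selection acts on the destination column state
  D * rep(f, each = nrow(D))
}

#' @export
print.mig_invasion <- function(x, ...) {
  cat("<mig_invasion> modifier type: ", x$type, "\n", sep = "")
  cat("  lambda = ", format(x$lambda, digits = 10),
      "  selection = ", format(x$selection, digits = 6),
      "  (max possible ", format(x$selection_max, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Tidy an invasion analysis
#'
#' @param x A `mig_invasion`.
#' @param ... Unused.
#' @return A one-row tibble: modifier type, lambda, selection coefficient,
#'   theoretical maximum, their ratio, and the resident loads.
#' @export
tidy.mig_invasion <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    lambda = x$lambda,
    selection = x$selection,
    selection_max = x$selection_max,
    fraction_of_max = x$selection / x$selection_max,
    load1 = x$eq$load[1L],
    load2 = x$eq$load[2L]
  )
}

#' @rdname tidy.mig_invasion
#' @export
glance.mig_invasion <- function(x, ...) {
  p <- x$eq$params
  dplyr::bind_cols(
    tibble::tibble(k = p$k, S = p$S, m1 = p$m[1L], m2 = p$m[2L],
                   phi = p$phi),
    tidy(x)
  )
}
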