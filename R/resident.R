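#' One generation of the two-deme life cycle
#'
#' Advances gametic-census haplotype frequencies by one generation of the
#' resident life cycle: random union of gametes (syngamy) within the natal
#' deme, diploid migration between demes, viability selection in the deme of
#' arrival, then meiosis through the gamete-production tensor. Frequencies
#' are renormalised by the post-selection mean fitness of each deme, which is
#' returned alongside the new state.
#'
#' @param x1,x2 Haplotype frequency vectors (length `2^k`, summing to 1) for
#'   demes 1 and 2, censused at the haploid gametic stage.
#' @param ft A [fitness_table()].
#' @param gt A [gamete_tensor()] built on the resident k-locus map.
#' @param m Migration rates, length 2 (`m[d]` is the emigration rate out of
#'   deme d); a scalar is used for both demes.
#' @return List with the next `x1`, `x2` and `w_bar` (the per-deme mean
#'   fitness used as the normaliser).
#' @export
life_cycle_step <- function(x1, x2, ft, gt, m) {
  stopifnot(inherits(ft, "fitness_table"), inherits(gt, "gamete_tensor"))
  m <- check_migration(m)
  if (abs(sum(x1) - 1) > 1e-8 || abs(sum(x2) - 1) > 1e-8 ||
      any(x1 < -1e-12) || any(x2 < -1e-12)) {
    stop("haplotype frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  Gmat <- gamete_matrix(gt)
  P1 <- outer(x1, x1)
  P2 <- outer(x2, x2)
  M1 <- ((1 - m[1L]) * P1 + m[2L] * P2) * ft$W[[1L]]
  M2 <- ((1 - m[2L]) * P2 + m[1L] * P1) * ft$W[[2L]]
  y1 <- as.vector(Gmat %*% as.vector(M1))
  y2 <- as.vector(Gmat %*% as.vector(M2))
  w_bar <- c(sum(y1), sum(y2))
  list(x1 = y1 / w_bar[1L], x2 = y2 / w_bar[2L], w_bar = w_bar)
}

check_migration <- function(m) {
  if (length(m) == 1L) m <- rep(m, 2L)
  if (length(m) != 2L || any(m < 0) || any(m > 1)) {
    stop("`m` must be one or two rates in [0, 1]", call. = FALSE)
  }
  as.numeric(m)
}

#' Solve the resident migration-selection equilibrium
#'
#' Iterates the two-deme life-cycle recursion from a locally adapted start to
#' the polymorphic migration-selection balance. Each deme is initialised with
#' its locally favored haplotype at frequency 0.9999 and the residual 0.0001
#' spread at random (seeded uniform draws, then normalised) over the other
#' haplotypes — a deliberately asymmetric start that avoids the symmetric but
#' unstable equilibrium. Iteration stops when the largest per-generation
#' change in any haplotype frequency drops below `tol`, or after `max_gen`
#' generations (the result is then flagged unconverged, not an error).
#'
#' Results are memoised per parameterisation (including the seed).
#'
#' @param k Number of local-adaptation loci (1-5).
#' @param S Total fitness cost of the most maladapted genotype.
#' @param m Migration rate(s); scalar or per-deme pair.
#' @param r Recombination between adjacent local-adaptation loci (scalar or
#'   length `k - 1`).
#' @param r_m Recombination between the modifier position and locus 1. Plays
#'   no role in the resident dynamics (no modifier segregates); it is stored
#'   as the resident value that a null modifier inherits.
#' @param theta,phi Dominance and epistasis parameters (deme-1 polarity).
#' @param tol Convergence tolerance on the max absolute frequency change.
#' @param max_gen Generation cap.
#' @param seed Integer seed for the randomised initial condition.
#' @param cache Reuse a memoised equilibrium when available.
#' @return An object of class `mig_equilibrium`: haplotype frequencies `x`
#'   (list of two vectors), `w_bar`, `load` (`1 - w_bar`), `converged`,
#'   `generations`, `max_delta`, and `params`.
#' @examples
#' eq <- solve_equilibrium(k = 2, S = 0.1, m = 0.05)
#' glance(eq)
#' @export
solve_equilibrium <- function(k = 2, S = 0.1, m = 0.05, r = 0.5, r_m = 0,
                              theta = 0, phi = 0, tol = 1e-8, max_gen = 5000,
                              seed = 1, cache = TRUE) {
  m <- check_migration(m)
  map <- linkage_map(k = k, r = r)
  spec <- fitness_spec(S = S, theta = theta, phi = phi, k = map$k)
  r_m <- check_rec(r_m, "r_m")
  key <- paste("EQ", map$k, format(S, digits = 17),
               paste(format(m, digits = 17), collapse = ","),
               paste(format(map$rec, digits = 17), collapse = ","),
               paste(format(spec$theta, digits = 17), collapse = ","),
               format(spec$phi, digits = 17),
               format(tol, digits = 17), max_gen, seed, sep = "|")
  if (cache) {
    hit <- cache_get(key)
    if (!is.null(hit)) return(hit)
  }

  ft <- fitness_table(spec)
  gt <- gamete_tensor(map)
  N <- 2L^map$k

  init <- with_seed(seed, {
    lapply(1:2, function(d) {
      fav <- if (d == 1L) N else 1L     # all-ones in deme 1, all-zeros in deme 2
      x <- stats::runif(N)
      x[fav] <- 0
      x <- x / sum(x) * 1e-4
      x[fav] <- 0.9999
      x
    })
  })
  x1 <- init[[1L]]
  x2 <- init[[2L]]

  max_delta <- Inf
  gen <- 0L
  w_bar <- c(NA_real_, NA_real_)
  while (gen < max_gen && max_delta >= tol) {
    nxt <- life_cycle_step(x1, x2, ft, gt, m)
    if (anyNA(nxt$x1) || anyNA(nxt$x2) || any(nxt$x1 < 0) || any(nxt$x2 < 0)) {
      stop("recursion produced invalid frequencies", call. = FALSE)
    }
    max_delta <- max(abs(nxt$x1 - x1), abs(nxt$x2 - x2))
    x1 <- nxt$x1
    x2 <- nxt$x2
    w_bar <- nxt$w_bar
    gen <- gen + 1L
  }

  out <- structure(
    list(
      x = list(x1, x2),
      w_bar = w_bar,
      load = 1 - w_bar,
      converged = max_delta < tol,
      generations = gen,
      max_delta = max_delta,
      params = list(k = map$k, S = S, m = m, r = map$rec, r_m = r_m,
                    theta = spec$theta, phi = spec$phi,
                    tol = tol, max_gen = max_gen, seed = seed)
    ),
    class = "mig_equilibrium"
  )
  if (cache) cache_set(key, out)
  out
}

# run code with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.mig_equilibrium <- function(x, ...) {
  p <- x$params
  cat("<mig_equilibrium> k = ", p$k, ", S = ", p$S, ", m = (",
      paste(format(p$m), collapse = ", "), "), phi = ", p$phi, "\n", sep = "")
  cat("  ", if (x$converged) "converged" else "NOT converged",
      " in ", x$generations, " generations (max delta ",
      format(x$max_delta, digits = 3), ")\n", sep = "")
  cat("  mean fitness: ", paste(format(x$w_bar, digits = 8), collapse = ", "),
      "; load: ", paste(format(x$load, digits = 8), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Migration load at equilibrium
#'
#' The load in deme d is `L_d = 1 - w_bar_d`, the shortfall of mean fitness
#' below the locally best genotype's fitness of 1.
#'
#' @param eq A [solve_equilibrium()] result.
#' @return Numeric length-2 vector `(L_1, L_2)`. Unconverged input attaches a
#'   warning.
#' @export
migration_load <- function(eq) {
  stopifnot(inherits(eq, "mig_equilibrium"))
  if (!eq$converged) {
    warning("equilibrium not converged; load is provisional", call. = FALSE)
  }
  eq$load
}

#' Check that local-adaptation polymorphism is maintained
#'
#' TRUE iff every local-adaptation locus still segregates for both alleles,
#' each at frequency at least `threshold`, in at least one deme. Useful when
#' exploring asymmetric parameters, where migration-selection balance can
#' collapse to fixation.
#'
#' @param eq A [solve_equilibrium()] result.
#' @param threshold Minimum minor-allele frequency.
#' @return Logical flag.
#' @export
check_polymorphic <- function(eq, threshold = 1e-3) {
  stopifnot(inherits(eq, "mig_equilibrium"))
  k <- eq$params$k
  B <- all_haplotypes(k)
  ok <- vapply(seq_len(k), function(i) {
    any(vapply(1:2, function(d) {
      p <- sum(eq$x[[d]] * B[, i])
      min(p, 1 - p) >= threshold
    }, logical(1L)))
  }, logical(1L))
  all(ok)
}

#' Tidy the equilibrium haplotype frequencies
#'
#' @param x A `mig_equilibrium`.
#' @param ... Unused.
#' @return A tibble with one row per (deme, haplotype): index, allele string
#'   (locus 1 first, 1 = deme-1 adapted), and frequency.
#' @export
tidy.mig_equilibrium <- function(x, ...) {
  k <- x$params$k
  B <- all_haplotypes(k)
  bits <- apply(B, 1L, paste, collapse = "")
  purrr::map_dfr(1:2, function(d) {
    tibble::tibble(
      deme = d,
      haplotype = 0:(2L^k - 1L),
      alleles = bits,
      frequency = x$x[[d]]
    )
  })
}

#' One-row summary of an equilibrium
#'
#' @param x A `mig_equilibrium`.
#' @param ... Unused.
#' @return A tibble with the parameters, mean fitnesses, loads, convergence
#'   metadata and the polymorphism flag.
#' @export
glance.mig_equilibrium <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    k = p$k, S = p$S, m1 = p$m[1L], m2 = p$m[2L], phi = p$phi,
    w_bar1 = x$w_bar[1L], w_bar2 = x$w_bar[2L],
    load1 = x$load[1L], load2 = x$load[2L],
    converged = x$converged, generations = x$generations,
    max_delta = x$max_delta,
    polymorphic = check_polymorphic(x)
  )
}

#' Export an equilibrium as CSV plus JSON metadata
#'
#' @param eq A `mig_equilibrium`.
#' @param csv Path for the per-haplotype frequency table.
#' @param json Optional path for a metadata sidecar (parameters, mean
#'   fitness, load, convergence, seed).
#' @return `eq`, invisibly.
#' @export
write_equilibrium <- function(eq, csv, json = NULL) {
  stopifnot(inherits(eq, "mig_equilibrium"))
  readr::write_csv(tidy(eq), csv)
  if (!is.null(json)) {
    meta <- c(eq$params,
              list(w_bar = eq$w_bar, load = eq$load,
                   converged = eq$converged, generations = eq$generations,
                   max_delta = eq$max_delta))
    jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(eq)
}
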