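#' Probability of a crossover pattern on a linear map
#'
#' Each interval between adjacent loci experiences an independent chance of
#' crossing over, so a full pattern of crossovers has probability equal to the
#' product over intervals of `r_t` (crossover) or `1 - r_t` (no crossover).
#'
#' @param rec Recombination vector, one probability per interval, each in
#'   \[0, 0.5\].
#' @param pattern 0/1 vector, 1 where a crossover occurs in that interval.
#' @return The pattern probability.
#' @examples
#' crossover_pattern_probability(c(0.1, 0.2), c(1, 0))  # 0.1 * 0.8
#' @export
crossover_pattern_probability <- function(rec, pattern) {
  rec <- check_rec(rec, "rec")
  if (length(pattern) != length(rec)) {
    stop("`pattern` must have one entry per interval", call. = FALSE)
  }
  if (!all(pattern %in% c(0, 1))) stop("`pattern` must be 0/1", call. = FALSE)
  prod(ifelse(pattern == 1, rec, 1 - rec))
}

#' Build the gamete-production tensor
#'
#' For every ordered pair of parental haplotypes `(i, j)` on a linear map,
#' computes the exact probability distribution over gamete haplotypes under
#' Mendelian segregation and independent interval crossovers (two-strand
#' model, no interference). The result is a three-way array
#' `G[l, i, j]`: the probability that a parent carrying haplotypes `i` and
#' `j` produces a gamete `l` (indices are haplotype index + 1).
#'
#' Construction sums over the 2^n equally structured strand-origin masks: the
#' gamete copies each locus from one of the two parental haplotypes, the
#' starting strand is chosen with probability 1/2, and the origin switches
#' between strands wherever a crossover occurs. Probabilities are exact
#' floating point; no Monte Carlo is involved. Tensors are cached per
#' recombination vector, so repeated calls with the same map are free.
#'
#' @param map A [linkage_map()] with at most 6 loci (5 local-adaptation loci
#'   plus the modifier).
#' @return An object of class `gamete_tensor`: list with `G` (the
#'   `2^n x 2^n x 2^n` array), `n_loci`, and `rec`.
#' @examples
#' gt <- gamete_tensor(linkage_map(k = 2, r = 0.2))
#' gamete_distribution(gt, hap_encode(c(1, 1)), hap_encode(c(0, 0)))
#' @export
gamete_tensor <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  n <- map$n_loci
  if (n > 6L) stop("unsupported size: maps with more than 6 loci", call. = FALSE)
  key <- paste0("G:", n, ":", paste(format(map$rec, digits = 17), collapse = ","))
  cached <- cache_get(key)
  if (!is.null(cached)) return(cached)

  N <- 2L^n
  idx <- 0:(N - 1L)
  G <- array(0, dim = c(N, N, N))
  # parent-origin masks: bit b = 1 means locus b copied from haplotype i
  ij <- expand.grid(i = idx, j = idx)
  full <- N - 1L
  for (mask in idx) {
    bits <- hap_decode(mask, n)[1L, ]
    # crossover occurs where origin switches between adjacent loci
    switches <- if (n > 1L) abs(diff(bits)) else integer(0)
    p <- 0.5 * prod(ifelse(switches == 1L, map$rec, 1 - map$rec))
    if (p == 0) next
    gam <- bitwOr(bitwAnd(ij$i, mask), bitwAnd(ij$j, bitwXor(full, mask)))
    G[cbind(gam + 1L, ij$i + 1L, ij$j + 1L)] <-
      G[cbind(gam + 1L, ij$i + 1L, ij$j + 1L)] + p
  }
  out <- structure(list(G = G, n_loci = n, rec = map$rec), class = "gamete_tensor")
  cache_set(key, out)
  out
}

#' @export
print.gamete_tensor <- function(x, ...) {
  N <- 2L^x$n_loci
  cat("<gamete_tensor> ", x$n_loci, " loci, ", N, "^3 = ", N^3, " entries\n",
      sep = "")
  cat("  rec vector: ", paste(format(x$rec), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gamete distribution of one parental genotype
#'
#' @param gt A [gamete_tensor()].
#' @param h1,h2 Parental haplotype indices.
#' @param as_tibble Return a tibble (gamete index, probability) instead of a
#'   bare numeric vector.
#' @return Probability vector over the `2^n` gametes (sums to 1), or a tibble.
#' @export
gamete_distribution <- function(gt, h1, h2, as_tibble = FALSE) {
  stopifnot(inherits(gt, "gamete_tensor"))
  N <- 2L^gt$n_loci
  if (h1 < 0 || h1 >= N || h2 < 0 || h2 >= N) stop("haplotype index out of range", call. = FALSE)
  p <- gt$G[, h1 + 1L, h2 + 1L]
  if (!as_tibble) return(p)
  tibble::tibble(gamete = 0:(N - 1L), probability = p)
}

# flat (N x N^2) view used by the recursion: row l, column (i, j) with i fastest
gamete_matrix <- function(gt) {
  N <- 2L^gt$n_loci
  matrix(as.vector(gt$G), nrow = N)
}
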