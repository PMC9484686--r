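#' Specify the fitness function
#'
#' Diploid fitness in each habitat is driven by the *effective* fraction of
#' maladapted alleles, computed in two logistic stages: a per-locus dominance
#' stage and a genome-wide epistasis stage. The parameterisation is polarised
#' for deme 1; deme 2 is obtained by complementing allele states and negating
#' `theta` and `phi`, the symmetric-effects assumption under which the fully
#' polymorphic equilibrium is stable.
#'
#' @param S Total fitness cost of the most maladapted genotype, in \[0, 1):
#'   the least-fit genotype has fitness `1 - S` (S = 0, useful for cost-free
#'   modifier carriers, makes every genotype equally fit).
#' @param theta Dominance parameter(s), one per local-adaptation locus
#'   (recycled from a scalar). `theta = 0` is additivity; `theta > 0` makes
#'   the deme-1 adapted allele dominant in deme 1.
#' @param phi Epistasis parameter. `phi = 0` makes fitness multiplicative
#'   across loci; `phi > 0` masks maladaptation in deme 1 (diminishing-returns
#'   epistasis there, synergistic in deme 2).
#' @param k Number of local-adaptation loci.
#' @return An object of class `fitness_spec`.
#' @examples
#' fitness_spec(S = 0.1, theta = 0, phi = 0, k = 2)
#' @export
fitness_spec <- function(S, theta = 0, phi = 0, k) {
  if (!is.numeric(S) || length(S) != 1L || S < 0 || S >= 1) {
    stop("`S` must be a single value in [0, 1)", call. = FALSE)
  }
  k <- as.integer(k)
  if (length(theta) == 1L) theta <- rep(theta, k)
  if (length(theta) != k) stop("`theta` must have length 1 or k", call. = FALSE)
  if (!all(is.finite(theta)) || !is.finite(phi) || length(phi) != 1L) {
    stop("`theta` and `phi` must be finite", call. = FALSE)
  }
  structure(list(S = S, theta = as.numeric(theta), phi = as.numeric(phi), k = k),
            class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat("<fitness_spec> S = ", x$S, ", theta = (",
      paste(format(x$theta), collapse = ", "), "), phi = ", x$phi, "\n", sep = "")
  invisible(x)
}

#' Effective adapted fraction of a heterozygote
#'
#' The logistic dominance kernel: a heterozygote at a locus with dominance
#' parameter `theta` behaves as if a fraction `1 / (1 + exp(-theta))` of its
#' two alleles were locally adapted. `theta = 0` gives exactly 1/2
#' (additivity); large positive `theta` makes the adapted allele fully
#' dominant.
#'
#' @param theta Dominance parameter (vectorised).
#' @return Value(s) in (0, 1).
#' @export
het_effect <- function(theta) stats::plogis(theta)

#' Aggregate dominance stage: effective maladapted fraction
#'
#' Averages per-locus contributions over the k local-adaptation loci, reading
#' each locus of the diploid genotype in the polarity of `deme`: a homozygote
#' for the deme-favored allele contributes 0, a homozygote for the
#' deme-disfavored allele contributes 1, and a heterozygote contributes
#' `1 - het_effect(theta_d)` where `theta_d` is the locus' dominance parameter
#' in that deme's polarity (`theta` in deme 1, `-theta` in deme 2).
#'
#' @param a1,a2 0/1 local-adaptation allele vectors of the two haplotypes
#'   (deme-1 polarity, length k).
#' @param theta Dominance parameters, length k.
#' @param deme Habitat, 1 or 2.
#' @return The effective fraction of maladapted alleles, in \[0, 1\].
#' @export
dominance_aggregate <- function(a1, a2, theta, deme = 1) {
  deme <- check_deme(deme)
  k <- length(a1)
  stopifnot(length(a2) == k, length(theta) == k)
  if (deme == 2L) {
    a1 <- 1 - a1
    a2 <- 1 - a2
    theta <- -theta
  }
  het <- a1 != a2
  # favored homozygote -> 0, disfavored homozygote -> 1, het -> logistic term
  contrib <- ifelse(het, 1 - het_effect(theta), 1 - a1)
  mean(contrib)
}

#' Epistasis stage: logit-shift of the maladapted fraction
#'
#' Applies the genome-wide epistasis transform
#' `l = logistic(logit(dom) - phi)`: the identity when `phi = 0`, pushing the
#' effective maladapted fraction towards 0 as `phi` grows. The boundary
#' values `dom = 0` and `dom = 1` are fixed points for every finite `phi`
#' (handled without infinite arithmetic), preserving continuity with the
#' `phi = 0` identity.
#'
#' @param dom Effective maladapted fraction(s) in \[0, 1\].
#' @param phi Epistasis parameter in the polarity of the deme being evaluated
#'   (pass `-phi` for deme 2).
#' @return Value(s) in \[0, 1\].
#' @export
epistasis_transform <- function(dom, phi) {
  if (any(dom < 0 | dom > 1)) stop("`dom` must lie in [0, 1]", call. = FALSE)
  out <- dom
  inner <- dom > 0 & dom < 1
  out[inner] <- stats::plogis(stats::qlogis(dom[inner]) - phi)
  out
}

#' Fitness of one diploid genotype
#'
#' `W = (1 - S)^l`, evaluated in log space: `l` is the effective maladapted
#' fraction after the dominance and epistasis stages, so `l = 0` gives
#' fitness 1 and `l = 1` gives `1 - S`.
#'
#' @param h1,h2 Local-adaptation haplotype indices (k-locus encoding; any
#'   modifier bit must be stripped first, fitness ignores it).
#' @param spec A [fitness_spec()].
#' @param deme Habitat, 1 or 2.
#' @return Fitness in `[1 - S, 1]`.
#' @export
genotype_fitness <- function(h1, h2, spec, deme = 1) {
  stopifnot(inherits(spec, "fitness_spec"))
  a1 <- hap_decode(h1, spec$k)[1L, ]
  a2 <- hap_decode(h2, spec$k)[1L, ]
  dom <- dominance_aggregate(a1, a2, spec$theta, deme)
  l <- epistasis_transform(dom, if (deme == 1L) spec$phi else -spec$phi)
  exp(l * log(1 - spec$S))
}

#' Fitness table over all diploid genotypes
#'
#' Evaluates fitness for every ordered pair of the `2^k` local-adaptation
#' haplotypes in both demes. Tables are symmetric in the two haplotypes and
#' the deme-2 table is the allele-complement image of the deme-1 table under
#' `(theta, phi) -> (-theta, -phi)`.
#'
#' @param spec A [fitness_spec()].
#' @return An object of class `fitness_table`: list with `W` (list of two
#'   `2^k x 2^k` matrices, one per deme), `l` (the corresponding effective
#'   maladapted fractions), and `spec`.
#' @export
fitness_table <- function(spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  k <- spec$k
  B <- all_haplotypes(k)           # 2^k x k allele matrix, deme-1 polarity
  N <- 2L^k
  l <- vector("list", 2L)
  W <- vector("list", 2L)
  for (d in 1:2) {
    A <- if (d == 1L) B else 1L - B
    th <- if (d == 1L) spec$theta else -spec$theta
    ph <- if (d == 1L) spec$phi else -spec$phi
    dom <- matrix(0, N, N)
    for (i in seq_len(k)) {
      a <- A[, i]
      hetm <- outer(a, a, "!=")
      # disfavored homozygote (a = 0 on both) contributes 1
      dom <- dom + ifelse(hetm, 1 - het_effect(th[i]), outer(1 - a, 1 - a, "*"))
    }
    dom <- dom / k
    l[[d]] <- epistasis_transform(dom, ph)
    W[[d]] <- exp(l[[d]] * log(1 - spec$S))
  }
  structure(list(W = W, l = l, spec = spec), class = "fitness_table")
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("<fitness_table> ", nrow(x$W[[1L]]), " haplotypes x 2 demes; W in [",
      format(1 - x$spec$S), ", 1]\n", sep = "")
  invisible(x)
}

#' Tidy a fitness table
#'
#' @param x A [fitness_table()].
#' @param ... Unused.
#' @return A tibble with one row per (deme, h1, h2): the effective maladapted
#'   fraction `l` and fitness `W`.
#' @export
tidy.fitness_table <- function(x, ...) {
  N <- nrow(x$W[[1L]])
  purrr::map_dfr(1:2, function(d) {
    tibble::tibble(
      deme = d,
      h1 = rep(0:(N - 1L), times = N),
      h2 = rep(0:(N - 1L), each = N),
      l = as.vector(x$l[[d]]),
      W = as.vector(x$W[[d]])
    )
  })
}
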