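#' Define a linear linkage map
#'
#' A map is an ordered set of loci on a single linear chromosome: optionally a
#' modifier locus in position 1, followed by `k` local-adaptation loci.
#' Adjacent loci recombine independently with the probabilities in the
#' recombination vector (no crossover interference), so `r = 0.5` everywhere
#' recovers freely segregating loci.
#'
#' @param k Number of local-adaptation loci (1 to 5).
#' @param r Recombination probabilities between successive local-adaptation
#'   loci; a scalar is recycled to length `k - 1`. Each value in \[0, 0.5\].
#' @param r_m Recombination probability between the modifier locus and the
#'   first local-adaptation locus, or `NULL` for a map without a modifier
#'   locus. When present the modifier occupies position 1.
#'
#' @return An object of class `linkage_map` with fields `k`, `has_modifier`,
#'   `n_loci`, `positions`, and `rec` (the full recombination vector,
#'   `r_m` first when the modifier is present).
#' @examples
#' linkage_map(k = 3)                  # resident map, free recombination
#' linkage_map(k = 3, r = 0, r_m = 0)  # inversion-like: fully linked block
#' @export
linkage_map <- function(k, r = 0.5, r_m = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > 5) {
    stop("`k` must be a single integer between 1 and 5", call. = FALSE)
  }
  k <- as.integer(k)
  r <- check_rec(r, "r")
  if (k == 1L) {
    r <- numeric(0)
  } else if (length(r) == 1L) {
    r <- rep(r, k - 1L)
  } else if (length(r) != k - 1L) {
    stop("`r` must have length 1 or k - 1 = ", k - 1L, call. = FALSE)
  }
  has_modifier <- !is.null(r_m)
  if (has_modifier) {
    r_m <- check_rec(r_m, "r_m")
    if (length(r_m) != 1L) stop("`r_m` must be a single value", call. = FALSE)
  }
  n_loci <- k + as.integer(has_modifier)
  positions <- c(if (has_modifier) "M", paste0("L", seq_len(k)))
  structure(
    list(
      k = k,
      has_modifier = has_modifier,
      n_loci = n_loci,
      positions = positions,
      rec = c(if (has_modifier) r_m, r)
    ),
    class = "linkage_map"
  )
}

check_rec <- function(r, name) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r > 0.5)) {
    stop("`", name, "` entries must lie in [0, 0.5]", call. = FALSE)
  }
  as.numeric(r)
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("<linkage_map> ", x$n_loci, " loci: ",
      paste(x$positions, collapse = " - "), "\n", sep = "")
  if (x$n_loci > 1L) {
    cat("  rec vector: ", paste(format(x$rec), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Encode and decode haplotypes
#'
#' Haplotypes over an `n`-locus map are stored as integer indices in
#' `[0, 2^n)`. The bit order is fixed: position 1 of the map (the modifier,
#' when present) is the most significant bit. Allele value 1 denotes the
#' allele locally adapted in deme 1 (for the modifier locus, the mutant
#' modifier allele); allele 0 is the allele locally adapted in deme 2.
#'
#' @param alleles Integer vector of 0/1 allele states, position 1 first.
#' @param index Haplotype index (or vector of indices) in `[0, 2^n)`.
#' @param n_loci Number of loci on the map.
#'
#' @return `hap_encode()` returns the integer index; `hap_decode()` returns a
#'   matrix with one row per index and one 0/1 column per locus.
#' @examples
#' hap_encode(c(1, 0, 1))        # 5
#' hap_decode(5, n_loci = 3)
#' @export
hap_encode <- function(alleles) {
  if (anyNA(alleles) || !all(alleles %in% c(0, 1))) {
    stop("alleles must be 0/1", call. = FALSE)
  }
  n <- length(alleles)
  if (n < 1L || n > 6L) stop("allele vectors must have 1 to 6 entries", call. = FALSE)
  sum(as.integer(alleles) * 2L^((n - 1L):0L))
}

#' @rdname hap_encode
#' @export
hap_decode <- function(index, n_loci) {
  n_loci <- as.integer(n_loci)
  if (any(index < 0) || any(index >= 2^n_loci)) {
    stop("index out of range for ", n_loci, " loci", call. = FALSE)
  }
  out <- vapply(
    (n_loci - 1L):0L,
    function(b) bitwAnd(bitwShiftR(as.integer(index), b), 1L),
    integer(length(index))
  )
  matrix(out, nrow = length(index), dimnames = list(NULL, NULL))
}

# 0/1 allele matrix for all 2^n haplotypes (row h+1 = haplotype h)
all_haplotypes <- function(n_loci) hap_decode(0:(2^n_loci - 1L), n_loci)

#' Count locally adapted alleles on a haplotype
#'
#' Counts, over the local-adaptation loci only (the modifier bit is ignored),
#' how many alleles are favored in the given deme. The two counts are
#' complementary: `adapted_count(h, 1) + adapted_count(h, 2) = k`.
#'
#' @param index Haplotype index (vectorised).
#' @param map A [linkage_map()].
#' @param deme Deme of reference, 1 or 2.
#' @return Integer vector of adapted-allele counts.
#' @export
adapted_count <- function(index, map, deme = 1) {
  stopifnot(inherits(map, "linkage_map"))
  deme <- check_deme(deme)
  bits <- hap_decode(index, map$n_loci)
  local <- bits[, (map$n_loci - map$k + 1L):map$n_loci, drop = FALSE]
  n1 <- as.integer(rowSums(local))
  if (deme == 1L) n1 else map$k - n1
}

check_deme <- function(deme) {
  if (!deme %in% c(1, 2)) stop("`deme` must be 1 or 2", call. = FALSE)
  as.integer(deme)
}

#' Classify zygosity of a diploid genotype at one locus
#'
#' A diploid genotype is an unordered pair of haplotypes. At each
#' local-adaptation locus it is heterozygous, homozygous for the deme-1
#' adapted allele, or homozygous for the deme-2 adapted allele.
#'
#' @param h1,h2 Haplotype indices.
#' @param map A [linkage_map()].
#' @param locus Local-adaptation locus label, 1..k (the modifier locus is not
#'   a valid target).
#' @return One of `"het"`, `"hom_adapted_1"`, `"hom_adapted_2"`.
#' @export
zygosity <- function(h1, h2, map, locus) {
  stopifnot(inherits(map, "linkage_map"))
  if (length(locus) != 1L || !locus %in% seq_len(map$k)) {
    stop("`locus` must name a local-adaptation locus (1..k)", call. = FALSE)
  }
  col <- (map$n_loci - map$k) + as.integer(locus)
  a1 <- hap_decode(h1, map$n_loci)[, col]
  a2 <- hap_decode(h2, map$n_loci)[, col]
  if (a1 != a2) "het" else if (a1 == 1L) "hom_adapted_1" else "hom_adapted_2"
}
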