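# Named constructors for the algebras of genetic inheritance: the Mendelian
# and generalized (left almost) gametic algebras, zygotic duplication, the
# two-allele mutation algebra with rates r and s, its Gonshor basis, and
# the noncommutative star algebras a_i * a_j = alpha a_i + alpha^2 a_j.

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.chk_not_char2 <- function(field, what) {
  if (.field_char(field) == 2)
    stop(what, " requires division by 2, which does not exist in ",
         "characteristic 2 (", format(field), ")", call. = FALSE)
}

#' The n-allele Mendelian gametic algebra
#'
#' Basis `a1..an` (one gamete per allele) with product
#' `a_i a_j = (a_i + a_j)/2`: each parental gamete is transmitted with
#' probability 1/2.  The tensor `gamma[i,j,k] = (d_ik + d_jk)/2` is
#' row-stochastic and symmetric, and every weight-1 element is idempotent
#' (a one-locus population is at equilibrium after a single round of random
#' mating).
#'
#' @param n Number of alleles (`n >= 2`).
#' @param field An ordered `laa_field` of characteristic not 2
#'   (default: rationals).
#' @return A `laa_algebra`.
#' @export
#' @examples
#' G <- mendelian_gametic(2)
#' multiply(G, basis_element(G, 1), basis_element(G, 2))  # (1/2, 1/2)
mendelian_gametic <- function(n, field = field_rational()) {
  n <- as.integer(n)
  if (n < 2) stop("need at least 2 alleles", call. = FALSE)
  .chk_not_char2(field, "the Mendelian gametic algebra")
  half <- sc_rat(field, 1, 2)
  one <- sc_one(field); zero <- sc_zero(field)
  gamma <- vector("list", n^3); dim(gamma) <- c(n, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    v <- zero
    if (k == i) v <- sc_add(v, half)
    if (k == j) v <- sc_add(v, half)
    gamma[[i, j, k]] <- v
  }
  algebra(field, paste0("a", seq_len(n)),
          structure(list(n = n, gamma = gamma), class = "laa_tensor"),
          provenance = list(constructor = "mendelian_gametic", n = n))
}

#' Validate a tensor as a (possibly left almost) gametic algebra
#'
#' Gametic structure constants are relative gene frequencies: every row
#' must sum to 1 and (on ordered fields) lie in `[0, 1]`.  The classical
#' definition also demands the symmetry `gamma[i,j,k] = gamma[j,i,k]`
#' (mating is commutative); the left almost variant drops exactly that
#' constraint, permitting noncommutative gametic algebras.
#'
#' @param tensor A `laa_tensor` (or raw entries).
#' @param field The coefficient field.
#' @param la_variant If `TRUE`, the symmetry constraint is not required.
#' @return A validated `laa_algebra`.
#' @export
gametic_from_tensor <- function(tensor, field = field_rational(),
                                la_variant = FALSE) {
  if (!inherits(tensor, "laa_tensor")) tensor <- structure_tensor(field, tensor)
  checks <- c("row_stochastic", "bounded")
  if (!la_variant) checks <- c(checks, "symmetric")
  validate_tensor(field, tensor, checks)
  algebra(field, paste0("a", seq_len(tensor$n)), tensor,
          provenance = list(constructor = "gametic_from_tensor",
                            la_variant = la_variant))
}

#' Seeded random gametic algebra
#'
#' Fixture generator: draws each tensor row as a random composition
#' `c_1/q + ... + c_n/q = 1` with `q = denominator_bound`, so entries are
#' exact nonnegative rationals with denominator at most `q`.  With
#' `la_variant = FALSE` rows are drawn once per unordered pair and mirrored,
#' giving a commutative gametic algebra; with `la_variant = TRUE` all `n^2`
#' rows are independent, which is noncommutative with high probability.
#' Reproducible: the same seed always yields the same algebra.
#'
#' @param n Dimension.
#' @param field An ordered field (entries are embedded rationals).
#' @param seed Integer seed (mandatory, recorded in provenance).
#' @param la_variant Drop the symmetry constraint?
#' @param denominator_bound Common denominator of every row (default 8).
#' @return A validated `laa_algebra`.
#' @export
random_gametic <- function(n, field = field_rational(), seed,
                           la_variant = FALSE, denominator_bound = 8) {
  n <- as.integer(n)
  q <- as.integer(denominator_bound)
  if (q < 1) stop("denominator bound must be positive", call. = FALSE)
  if (!.field_ordered(field))
    stop("random gametic tensors need an ordered field", call. = FALSE)
  counts <- .with_seed(seed, {
    m <- array(0, dim = c(n, n, n))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!la_variant && j < i) { m[i, j, ] <- m[j, i, ]; next }
      m[i, j, ] <- as.numeric(stats::rmultinom(1, q, rep(1 / n, n)))
    }
    m
  })
  gamma <- vector("list", n^3); dim(gamma) <- c(n, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    gamma[[i, j, k]] <- sc_rat(field, counts[i, j, k], q)
  A <- gametic_from_tensor(
    structure(list(n = n, gamma = gamma), class = "laa_tensor"),
    field, la_variant = la_variant)
  A$provenance <- list(constructor = "random_gametic", n = n, seed = seed,
                       la_variant = la_variant, denominator_bound = q)
  A
}

#' Zygotic algebra by commutative duplication
#'
#' Given a row-stochastic gametic algebra on gametes `a1..an`, the zygotic
#' algebra lives on genotypes `e_ij` (unordered pairs, `i <= j`).  Mating
#' `e_ij x e_pq` draws one gamete from each parent's output distribution
#' and symmetrizes: the coefficient of `e_ks` is
#' `gamma[i,j,k] gamma[p,q,s] + gamma[i,j,s] gamma[p,q,k]` for `k < s` and
#' `gamma[i,j,k] gamma[p,q,k]` for `k = s`.  The result is again
#' row-stochastic.
#'
#' @param G A gametic `laa_algebra` with row-stochastic tensor.
#' @return A list with components `algebra` (the zygotic `laa_algebra`) and
#'   `index` (a data frame mapping each zygote label to its gamete pair).
#' @export
#' @examples
#' Z <- zygotic_duplicate(mendelian_gametic(2))
#' h <- basis_element(Z$algebra, 2)           # the heterozygote e12
#' multiply(Z$algebra, h, h)                  # (1/4, 1/2, 1/4)
zygotic_duplicate <- function(G) {
  field <- G$field
  n <- G$n
  validate_tensor(field, G$tensor, "row_stochastic")
  pairs <- do.call(rbind, lapply(seq_len(n), function(i)
    do.call(rbind, lapply(i:n, function(j) c(i, j)))))
  N <- nrow(pairs)                     # n(n+1)/2
  labels <- paste0("e", pairs[, 1], pairs[, 2])
  g <- G$tensor$gamma
  gamma <- vector("list", N^3); dim(gamma) <- c(N, N, N)
  for (u in seq_len(N)) for (v in seq_len(N)) {
    i <- pairs[u, 1]; j <- pairs[u, 2]
    p <- pairs[v, 1]; q <- pairs[v, 2]
    for (w in seq_len(N)) {
      k <- pairs[w, 1]; s <- pairs[w, 2]
      if (k == s) {
        val <- sc_mul(g[[i, j, k]], g[[p, q, k]])
      } else {
        val <- sc_add(sc_mul(g[[i, j, k]], g[[p, q, s]]),
                      sc_mul(g[[i, j, s]], g[[p, q, k]]))
      }
      gamma[[u, v, w]] <- val
    }
  }
  Z <- algebra(field, labels,
               structure(list(n = N, gamma = gamma), class = "laa_tensor"),
               provenance = list(constructor = "zygotic_duplicate",
                                 parent = G$provenance))
  index <- data.frame(label = labels, i = pairs[, 1], j = pairs[, 2],
                      stringsAsFactors = FALSE)
  list(algebra = Z, index = index)
}

#' The two-allele mutation algebra with rates r and s
#'
#' Gametic basis `(D, R)` where allele `D` mutates to `R` at rate `r` and
#' `R` back to `D` at rate `s` per generation.  The products are
#' `D^2 = (1-r) D + r R`,
#' `DR = RD = (1-r+s)/2 D + (1-s+r)/2 R`, and
#' `R^2 = s D + (1-s) R` — the `R^2` row mirrors the `D^2` row with the
#' roles of the alleles (and of `r`, `s`) swapped, the unique commutative
#' completion under which `(D - R)^2 = 0` (see [gonshor_basis()]).
#'
#' @param r,s Mutation rates in `[0, 1]` (fraction strings, scalars, or
#'   whole numbers).
#' @param field An ordered field of characteristic not 2.
#' @return A commutative 2-dimensional `laa_algebra` on basis `c("D", "R")`.
#' @export
#' @examples
#' Mu <- mutation_algebra("1/4", "1/2")
#' multiply(Mu, basis_element(Mu, 1), basis_element(Mu, 1))   # (3/4, 1/4)
mutation_algebra <- function(r, s, field = field_rational()) {
  .chk_not_char2(field, "the mutation algebra")
  if (!.field_ordered(field))
    stop("mutation rates live in [0, 1]: the field must be ordered", call. = FALSE)
  r <- scalar(field, r); s <- scalar(field, s)
  one <- sc_one(field); zero <- sc_zero(field)
  half <- sc_rat(field, 1, 2)
  for (rate in list(r, s)) {
    if (sc_sign(rate) < 0 || sc_sign(sc_sub(rate, one)) > 0)
      stop("mutation rates must lie in [0, 1]; got ", format(rate), call. = FALSE)
  }
  dd <- list(sc_sub(one, r), r)                                    # D^2
  dr <- list(sc_mul(half, sc_add(sc_sub(one, r), s)),              # DR = RD
             sc_mul(half, sc_add(sc_sub(one, s), r)))
  rr <- list(s, sc_sub(one, s))                                    # R^2
  gamma <- vector("list", 8); dim(gamma) <- c(2, 2, 2)
  rows <- list(dd, dr, dr, rr)   # (1,1), (1,2), (2,1), (2,2)
  idx <- 1
  for (i in 1:2) for (j in 1:2) {
    row <- rows[[(i - 1) * 2 + j]]
    gamma[[i, j, 1]] <- row[[1]]
    gamma[[i, j, 2]] <- row[[2]]
  }
  algebra(field, c("D", "R"),
          structure(list(n = 2L, gamma = gamma), class = "laa_tensor"),
          provenance = list(constructor = "mutation_algebra",
                            r = format(r), s = format(s)))
}

#' Gonshor basis of the mutation algebra
#'
#' Changes basis to `a = D`, `b = D - R`, in which the mutation algebra
#' takes the form `a^2 = a - r b`, `ab = (1-r-s)/2 b`, `b^2 = 0`.  The
#' weight-0 direction `b` is nilpotent: all mutation pressure acts along it.
#'
#' @param Mu An algebra produced by [mutation_algebra()].
#' @return A `laa_algebra` on basis `c("a", "b")`.
#' @export
gonshor_basis <- function(Mu) {
  if (is.null(Mu$provenance$constructor) ||
      Mu$provenance$constructor != "mutation_algebra")
    stop("gonshor_basis expects an algebra built by mutation_algebra()",
         call. = FALSE)
  M <- matrix(c(1, 0,    # a = D
                1, -1),  # b = D - R
              nrow = 2, byrow = TRUE)
  A <- change_of_basis(Mu, M, c("a", "b"))
  A$provenance <- list(constructor = "gonshor_basis",
                       r = Mu$provenance$r, s = Mu$provenance$s)
  A
}

#' The left almost star algebra a_i * a_j = alpha a_i + alpha^2 a_j
#'
#' Requires `alpha + alpha^2 = 1`, so that diagonal products collapse to
#' `a_i * a_i = a_i`.  Valid choices are the exact roots
#' `(-1 +/- sqrt(5))/2` in `Q(sqrt(5))` (see [golden_alpha()]) and the
#' generator `t` (or `t^2`) of `GF(4)`.  The resulting algebra is
#' noncommutative and nonassociative but satisfies the left invertive law
#' `(xy)z = (zy)x`, and every weight-1 element is idempotent.
#'
#' @param n Dimension (number of generators).
#' @param field The coefficient field.
#' @param alpha A scalar of `field` with `alpha + alpha^2 = 1`.
#' @return A `laa_algebra` with basis `a1..an`.
#' @export
#' @examples
#' M3 <- star_algebra(3, field_quadratic(5), golden_alpha())
#' multiply(M3, basis_element(M3, 1), basis_element(M3, 2))
star_algebra <- function(n, field = field_quadratic(5),
                         alpha = golden_alpha()) {
  n <- as.integer(n)
  if (n < 1) stop("dimension must be at least 1", call. = FALSE)
  alpha <- scalar(field, alpha)
  a2 <- sc_mul(alpha, alpha)
  if (!sc_eq(sc_add(alpha, a2), sc_one(field)))
    stop("alpha must satisfy alpha + alpha^2 = 1; alpha = ", format(alpha),
         " gives ", format(sc_add(alpha, a2)), call. = FALSE)
  zero <- sc_zero(field)
  gamma <- vector("list", n^3); dim(gamma) <- c(n, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    v <- zero
    if (k == i) v <- sc_add(v, alpha)
    if (k == j) v <- sc_add(v, a2)
    gamma[[i, j, k]] <- v
  }
  algebra(field, paste0("a", seq_len(n)),
          structure(list(n = n, gamma = gamma), class = "laa_tensor"),
          provenance = list(constructor = "star_algebra", n = n,
                            alpha = format(alpha)))
}

# the generator t of GF(4), a convenient alpha for star algebras there
#' The generator t of GF(4)
#'
#' Convenience accessor: returns the scalar `t` of
#' `GF(4) = GF(2^2)` built from `t^2 + t + 1`, which satisfies `t^3 = 1`
#' and `t + t^2 = 1` (so it is a valid star-algebra `alpha`).
#'
#' @return A list with components `field` (GF(4)) and `t` (the generator).
#' @export
gf4_generator <- function() {
  f <- make_finite_field(2, 2, c(1, 1, 1))
  list(field = f, t = scalar(f, c(0, 1)))
}
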