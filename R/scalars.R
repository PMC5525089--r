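# Exact scalar arithmetic over the three coefficient domains used by the
# genetic algebras in this package: the rationals Q, a real quadratic
# extension Q(sqrt(d)), and finite fields GF(p^k).  No floating point is
# used anywhere in this file; every value has a unique canonical
# representation so that equality is decidable by comparison.

# Integer magnitudes are carried in doubles; beyond 2^52 exactness would be
# at risk, so operations fail loudly instead of silently rounding.
.LAA_MAXINT <- 2^52

.laa_chk_int <- function(x) {
  if (any(!is.finite(x)) || any(abs(x) > .LAA_MAXINT))
    stop("exact integer overflow: intermediate magnitude exceeds 2^52; ",
         "reduce denominators or problem size", call. = FALSE)
  x
}

.laa_gcd1 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

# canonical fraction: positive denominator, reduced; vectorised componentwise
.rat_norm <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in exact rational", call. = FALSE)
  .laa_chk_int(num); .laa_chk_int(den)
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- mapply(.laa_gcd1, num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

.rat_add <- function(n1, d1, n2, d2) {
  g <- mapply(.laa_gcd1, d1, d2); g[g == 0] <- 1
  dd <- d1 / g
  .rat_norm(n1 * (d2 / g) + n2 * dd, dd * d2)
}

# cross-reduce before multiplying to keep magnitudes small
.rat_mul <- function(n1, d1, n2, d2) {
  g1 <- mapply(.laa_gcd1, n1, d2); g1[g1 == 0] <- 1
  g2 <- mapply(.laa_gcd1, n2, d1); g2[g2 == 0] <- 1
  .rat_norm((n1 / g1) * (n2 / g2), (d1 / g2) * (d2 / g1))
}

.laa_is_prime <- function(p) {
  if (p != round(p) || p < 2) return(FALSE)
  if (p < 4) return(TRUE)
  if (p %% 2 == 0) return(FALSE)
  f <- 3
  while (f * f <= p) {
    if (p %% f == 0) return(FALSE)
    f <- f + 2
  }
  TRUE
}

## ---- polynomial helpers over Z_p (coefficient vectors, ascending) ----

.pp_trim <- function(v) {
  while (length(v) > 1 && v[length(v)] == 0) v <- v[-length(v)]
  v
}

.pp_deg <- function(v) length(.pp_trim(v)) - 1L

.pp_is_zero <- function(v) all(v == 0)

.pp_mul <- function(a, b, p) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) if (a[i] != 0)
    out[i:(i + length(b) - 1L)] <- (out[i:(i + length(b) - 1L)] + a[i] * b) %% p
  .pp_trim(out %% p)
}

.ff_int_inv <- function(a, p) {
  a <- a %% p
  if (a == 0) stop("division by zero in GF(", p, ")", call. = FALSE)
  # p is small and prime: Fermat
  r <- 1; base <- a; e <- p - 2
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * base) %% p
    base <- (base * base) %% p
    e <- e %/% 2
  }
  r
}

# remainder of a modulo b over Z_p (b need not be monic)
.pp_mod <- function(a, b, p) {
  a <- .pp_trim(a %% p); b <- .pp_trim(b %% p)
  if (.pp_is_zero(b)) stop("polynomial division by zero", call. = FALSE)
  binv <- .ff_int_inv(b[length(b)], p)
  while (!.pp_is_zero(a) && length(a) >= length(b)) {
    d <- length(a) - length(b)
    c <- (a[length(a)] * binv) %% p
    a[(d + 1L):length(a)] <- (a[(d + 1L):length(a)] - c * b) %% p
    a <- .pp_trim(a)
  }
  a
}

.pp_quot <- function(a, b, p) {
  a <- .pp_trim(a %% p); b <- .pp_trim(b %% p)
  binv <- .ff_int_inv(b[length(b)], p)
  q <- numeric(max(1L, length(a) - length(b) + 1L))
  while (!.pp_is_zero(a) && length(a) >= length(b)) {
    d <- length(a) - length(b)
    c <- (a[length(a)] * binv) %% p
    q[d + 1L] <- c
    a[(d + 1L):length(a)] <- (a[(d + 1L):length(a)] - c * b) %% p
    a <- .pp_trim(a)
  }
  .pp_trim(q)
}

.pp_format <- function(v, var = "x") {
  v <- .pp_trim(v)
  if (.pp_is_zero(v)) return("0")
  terms <- character(0)
  for (i in seq_along(v)) {
    c <- v[i]
    if (c == 0) next
    pw <- i - 1L
    terms <- c(terms, if (pw == 0) as.character(c)
               else if (pw == 1) {
                 if (c == 1) var else paste0(c, var)
               } else {
                 if (c == 1) paste0(var, "^", pw) else paste0(c, var, "^", pw)
               })
  }
  paste(terms, collapse = " + ")
}

# irreducibility over Z_p for degree <= 4 by exhaustive factor search;
# returns NULL when irreducible, else a nontrivial factor (coeff vector)
.pp_find_factor <- function(mod, p) {
  k <- .pp_deg(mod)
  if (k <= 1) return(NULL)
  # linear factors <-> roots
  for (r in 0:(p - 1)) {
    val <- 0
    for (i in rev(seq_along(mod))) val <- (val * r + mod[i]) %% p
    if (val == 0) return(c((p - r) %% p, 1))   # x - r
  }
  if (k <= 3) return(NULL)
  if (k == 4) {
    # irreducible quadratic factors
    for (c0 in 0:(p - 1)) for (c1 in 0:(p - 1)) {
      q <- c(c0, c1, 1)
      if (!is.null(.pp_find_factor(q, p))) next  # reducible quadratic: skip
      if (.pp_is_zero(.pp_mod(mod, q, p))) return(q)
    }
    return(NULL)
  }
  stop("irreducibility check supports modulus degree <= 4", call. = FALSE)
}

## ---- field constructors ----

#' The field of rational numbers
#'
#' @return A `laa_field` object representing exact rational arithmetic.
#' @seealso [field_quadratic()], [make_finite_field()]
#' @export
#' @examples
#' f <- field_rational()
#' scalar(f, "1/2") + scalar(f, "1/3")
field_rational <- function() {
  structure(list(kind = "rational"), class = "laa_field")
}

#' A real quadratic extension Q(sqrt(d))
#'
#' Scalars are pairs `a + b*sqrt(d)` with exact rational `a`, `b`.  The
#' default `d = 5` gives the field containing the golden-ratio-type roots
#' `(-1 +/- sqrt(5))/2` of `x^2 + x - 1`.
#'
#' @param d A positive non-square integer discriminant.
#' @return A `laa_field` object.
#' @export
#' @examples
#' a <- golden_alpha(+1)
#' a + a * a    # exactly 1
field_quadratic <- function(d = 5) {
  d <- as.numeric(d)
  if (length(d) != 1 || d != round(d) || d < 2)
    stop("discriminant must be an integer >= 2", call. = FALSE)
  r <- floor(sqrt(d))
  if (r * r == d || (r + 1)^2 == d)
    stop("discriminant must be a non-square integer (", d, " is a square)",
         call. = FALSE)
  structure(list(kind = "quadratic", d = d), class = "laa_field")
}

#' Construct a finite field GF(p^k)
#'
#' Elements are polynomials in a generator `t` reduced modulo an irreducible
#' degree-`k` polynomial over `Z_p`.  The classical example is
#' `GF(4) = GF(2^2)` built from `t^2 + t + 1`, whose generator satisfies
#' `t^3 = 1` and `t + t^2 = 1`.
#'
#' @param p A prime characteristic.
#' @param k Extension degree (`k >= 1`, at most 4).
#' @param modulus Integer coefficients of the degree-`k` modulus polynomial,
#'   ascending (constant term first), length `k + 1`.  Must be irreducible
#'   over `Z_p`; a reducible modulus is rejected with a factor named.
#' @return A `laa_field` object with `p^k` elements.
#' @export
#' @examples
#' gf4 <- make_finite_field(2, 2, c(1, 1, 1))   # t^2 + t + 1
#' t <- scalar(gf4, c(0, 1))
#' element_order(gf4, t)                        # 3
make_finite_field <- function(p, k, modulus) {
  p <- as.numeric(p); k <- as.integer(k)
  if (!.laa_is_prime(p))
    stop("characteristic must be prime; got ", p, call. = FALSE)
  if (k < 1) stop("extension degree k must be >= 1", call. = FALSE)
  modulus <- as.numeric(modulus)
  if (length(modulus) != k + 1 || modulus[k + 1] %% p == 0)
    stop("modulus must have degree exactly k = ", k,
         " (ascending coefficients, length k + 1)", call. = FALSE)
  modulus <- modulus %% p
  fac <- .pp_find_factor(modulus, p)
  if (!is.null(fac))
    stop("modulus ", .pp_format(modulus), " is reducible over Z_", p,
         ": divisible by ", .pp_format(fac), call. = FALSE)
  # store monic
  lead_inv <- .ff_int_inv(modulus[k + 1], p)
  modulus <- (modulus * lead_inv) %% p
  structure(list(kind = "finite", p = p, k = k, modulus = modulus),
            class = "laa_field")
}

#' @export
print.laa_field <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.laa_field <- function(x, ...) {
  switch(x$kind,
         rational  = "Q (exact rationals)",
         quadratic = paste0("Q(sqrt(", x$d, "))"),
         finite    = paste0("GF(", x$p, "^", x$k, "), modulus ",
                            .pp_format(x$modulus, "t")))
}

.field_eq <- function(f1, f2) {
  if (f1$kind != f2$kind) return(FALSE)
  switch(f1$kind,
         rational  = TRUE,
         quadratic = f1$d == f2$d,
         finite    = f1$p == f2$p && f1$k == f2$k &&
                     identical(f1$modulus, f2$modulus))
}

.field_char <- function(f) if (f$kind == "finite") f$p else 0

.field_ordered <- function(f) f$kind != "finite"

.field_card <- function(f) {
  if (f$kind != "finite") stop("field is infinite", call. = FALSE)
  f$p^f$k
}

## ---- scalars ----

.sc <- function(f, num, den = NULL) {
  structure(list(f = f, num = num, den = den), class = "laa_scalar")
}

sc_zero <- function(f) switch(f$kind,
  rational  = .sc(f, 0, 1),
  quadratic = .sc(f, c(0, 0), c(1, 1)),
  finite    = .sc(f, numeric(f$k)))

sc_one <- function(f) switch(f$kind,
  rational  = .sc(f, 1, 1),
  quadratic = .sc(f, c(1, 0), c(1, 1)),
  finite    = .sc(f, c(1, numeric(f$k - 1))))

# embed an exact integer fraction num/den into any field
sc_rat <- function(f, num, den = 1) {
  if (num != round(num) || den != round(den))
    stop("sc_rat expects whole numbers", call. = FALSE)
  switch(f$kind,
    rational = {
      r <- .rat_norm(num, den); .sc(f, r$num, r$den)
    },
    quadratic = {
      r <- .rat_norm(num, den); .sc(f, c(r$num, 0), c(r$den, 1))
    },
    finite = {
      d <- den %% f$p
      if (d == 0)
        stop("1/", den, " does not exist in characteristic ", f$p, call. = FALSE)
      v <- numeric(f$k)
      v[1] <- ((num %% f$p) * .ff_int_inv(d, f$p)) %% f$p
      .sc(f, v)
    })
}

sc_int <- function(f, n) sc_rat(f, n, 1)

.sc_chk_field <- function(x, y) {
  if (!.field_eq(x$f, y$f))
    stop("scalars belong to different fields: ", format(x$f), " vs ",
         format(y$f), call. = FALSE)
}

sc_add <- function(x, y) {
  .sc_chk_field(x, y)
  f <- x$f
  if (f$kind == "finite") return(.sc(f, (x$num + y$num) %% f$p))
  r <- .rat_add(x$num, x$den, y$num, y$den)
  .sc(f, r$num, r$den)
}

sc_neg <- function(x) {
  f <- x$f
  if (f$kind == "finite") return(.sc(f, (-x$num) %% f$p))
  .sc(f, -x$num, x$den)
}

sc_sub <- function(x, y) sc_add(x, sc_neg(y))

sc_mul <- function(x, y) {
  .sc_chk_field(x, y)
  f <- x$f
  switch(f$kind,
    rational = {
      r <- .rat_mul(x$num, x$den, y$num, y$den)
      .sc(f, r$num, r$den)
    },
    quadratic = {
      # (a1 + b1 s)(a2 + b2 s) = (a1 a2 + d b1 b2) + (a1 b2 + b1 a2) s
      t1 <- .rat_mul(x$num[1], x$den[1], y$num[1], y$den[1])
      t2 <- .rat_mul(x$num[2], x$den[2], y$num[2], y$den[2])
      t2 <- .rat_mul(t2$num, t2$den, f$d, 1)
      a  <- .rat_add(t1$num, t1$den, t2$num, t2$den)
      u1 <- .rat_mul(x$num[1], x$den[1], y$num[2], y$den[2])
      u2 <- .rat_mul(x$num[2], x$den[2], y$num[1], y$den[1])
      b  <- .rat_add(u1$num, u1$den, u2$num, u2$den)
      .sc(f, c(a$num, b$num), c(a$den, b$den))
    },
    finite = {
      v <- .pp_mul(x$num, y$num, f$p)
      v <- .pp_mod(v, f$modulus, f$p)
      .sc(f, c(v, numeric(f$k - length(v))))
    })
}

sc_is_zero <- function(x) {
  if (x$f$kind == "finite") all(x$num == 0) else all(x$num == 0)
}

sc_is_one <- function(x) sc_eq(x, sc_one(x$f))

sc_eq <- function(x, y) {
  .sc_chk_field(x, y)
  if (x$f$kind == "finite") return(identical(x$num, y$num))
  identical(x$num, y$num) && identical(x$den, y$den)
}

sc_inv <- function(x) {
  if (sc_is_zero(x)) stop("division by zero scalar", call. = FALSE)
  f <- x$f
  switch(f$kind,
    rational = {
      r <- .rat_norm(x$den, x$num); .sc(f, r$num, r$den)
    },
    quadratic = {
      # 1/(a + b s) = (a - b s) / (a^2 - d b^2); d non-square => nonzero norm
      a2 <- .rat_mul(x$num[1], x$den[1], x$num[1], x$den[1])
      b2 <- .rat_mul(x$num[2], x$den[2], x$num[2], x$den[2])
      b2 <- .rat_mul(b2$num, b2$den, f$d, 1)
      nr <- .rat_add(a2$num, a2$den, -b2$num, b2$den)
      ninv <- .rat_norm(nr$den, nr$num)
      a <- .rat_mul(x$num[1], x$den[1], ninv$num, ninv$den)
      b <- .rat_mul(-x$num[2], x$den[2], ninv$num, ninv$den)
      .sc(f, c(a$num, b$num), c(a$den, b$den))
    },
    finite = {
      # extended Euclid over Z_p[x]
      r0 <- .pp_trim(f$modulus); r1 <- .pp_trim(x$num)
      s0 <- 0; s1 <- 1   # polynomials, start as constants
      s0 <- numeric(1); s1 <- c(1)
      while (!.pp_is_zero(r1)) {
        q <- .pp_quot(r0, r1, f$p)
        r2 <- .pp_mod(r0, r1, f$p)
        qs1 <- .pp_mul(q, s1, f$p)
        ln <- max(length(s0), length(qs1))
        s2 <- (c(s0, numeric(ln - length(s0))) -
               c(qs1, numeric(ln - length(qs1)))) %% f$p
        r0 <- r1; r1 <- .pp_trim(r2)
        s0 <- s1; s1 <- .pp_trim(s2)
      }
      # r0 = gcd (a nonzero constant, since modulus irreducible)
      c0 <- .pp_trim(r0)
      if (length(c0) != 1) stop("internal: gcd with modulus not constant")
      v <- .pp_mul(s0, c(.ff_int_inv(c0[1], f$p)), f$p)
      v <- .pp_mod(v, f$modulus, f$p)
      .sc(f, c(v, numeric(f$k - length(v))))
    })
}

sc_div <- function(x, y) sc_mul(x, sc_inv(y))

sc_pow <- function(x, m) {
  m <- as.integer(m)
  if (m < 0) return(sc_inv(sc_pow(x, -m)))
  r <- sc_one(x$f); b <- x
  while (m > 0) {
    if (m %% 2L == 1L) r <- sc_mul(r, b)
    b <- sc_mul(b, b)
    m <- m %/% 2L
  }
  r
}

# sign of an element of an ordered field (rational or real quadratic)
sc_sign <- function(x) {
  f <- x$f
  if (!.field_ordered(f)) stop("finite fields are not ordered", call. = FALSE)
  if (f$kind == "rational") return(sign(x$num))
  a <- x$num[1]; b <- x$num[2]
  if (b == 0) return(sign(a))
  if (a == 0) return(sign(b))
  if (sign(a) == sign(b)) return(sign(a))
  # a, b opposite signs: compare a^2 with d b^2 exactly
  a2 <- .rat_mul(x$num[1], x$den[1], x$num[1], x$den[1])
  b2 <- .rat_mul(x$num[2], x$den[2], x$num[2], x$den[2])
  lhs <- a2$num * b2$den
  rhs <- f$d * b2$num * a2$den
  .laa_chk_int(lhs); .laa_chk_int(rhs)
  if (lhs == rhs) stop("internal: sqrt(", f$d, ") rational?")
  if (lhs > rhs) sign(a) else sign(b)
}

sc_abs <- function(x) if (sc_sign(x) < 0) sc_neg(x) else x

# exact square root within the field, or NULL when none exists there
sc_sqrt <- function(x) {
  f <- x$f
  if (f$kind == "finite") {
    for (e in field_elements(f)) if (sc_eq(sc_mul(e, e), x)) return(e)
    return(NULL)
  }
  if (sc_sign(x) < 0) return(NULL)
  .rat_sqrt <- function(num, den) {
    rn <- round(sqrt(num)); rd <- round(sqrt(den))
    if (rn * rn == num && rd * rd == den) c(rn, rd) else NULL
  }
  if (f$kind == "rational") {
    r <- .rat_sqrt(x$num, x$den)
    if (is.null(r)) return(NULL)
    return(.sc(f, r[1], r[2]))
  }
  # quadratic field: x = a + b sqrt(d)
  a <- list(num = x$num[1], den = x$den[1])
  b <- list(num = x$num[2], den = x$den[2])
  if (b$num == 0) {
    r <- .rat_sqrt(a$num, a$den)                     # rational square
    if (!is.null(r)) return(.sc(f, c(r[1], 0), c(r[2], 1)))
    ad <- .rat_norm(a$num, a$den * f$d)              # a/d a rational square?
    r <- .rat_sqrt(ad$num, ad$den)
    if (!is.null(r)) return(.sc(f, c(0, r[1]), c(1, r[2])))
    return(NULL)
  }
  # seek (u + v sqrt(d))^2 = a + b sqrt(d): u^2 + d v^2 = a, 2uv = b
  # => v^2 = (a - sqrt(a^2 - d b^2)) / (2d) (either branch)
  a2 <- .rat_mul(a$num, a$den, a$num, a$den)
  b2 <- .rat_mul(b$num, b$den, b$num, b$den)
  db2 <- .rat_mul(b2$num, b2$den, f$d, 1)
  disc <- .rat_add(a2$num, a2$den, -db2$num, db2$den)
  if (disc$num < 0) return(NULL)
  rs <- .rat_sqrt(disc$num, disc$den)
  if (is.null(rs)) return(NULL)
  for (sgn in c(1, -1)) {
    t <- .rat_add(a$num, a$den, sgn * rs[1], rs[2])
    v2 <- .rat_norm(t$num, t$den * 2 * f$d)
    rv <- .rat_sqrt(abs(v2$num), v2$den)
    if (v2$num < 0 || is.null(rv)) next
    if (rv[1] == 0) next
    u <- .rat_norm(b$num * rv[2], b$den * 2 * rv[1])  # u = b/(2v)
    cand <- .sc(f, c(u$num, rv[1]), c(u$den, rv[2]))
    if (sc_eq(sc_mul(cand, cand), x)) return(cand)
  }
  NULL
}

#' Multiplicative order of a nonzero finite-field element
#'
#' The smallest `m >= 1` with `x^m = 1`; always divides `p^k - 1`.
#'
#' @param f A finite `laa_field`.
#' @param x A nonzero scalar of `f`.
#' @return An integer order.
#' @export
#' @examples
#' gf4 <- make_finite_field(2, 2, c(1, 1, 1))
#' element_order(gf4, scalar(gf4, c(0, 1)))   # the generator t has order 3
element_order <- function(f, x) {
  if (f$kind != "finite") stop("element_order requires a finite field", call. = FALSE)
  x <- scalar(f, x)
  if (sc_is_zero(x)) stop("the zero element has no multiplicative order", call. = FALSE)
  acc <- x
  for (m in seq_len(.field_card(f) - 1)) {
    if (sc_is_one(acc)) return(m)
    acc <- sc_mul(acc, x)
  }
  stop("internal: order not found below field cardinality")
}

#' The exact roots of x^2 + x = 1 in Q(sqrt(5))
#'
#' Returns `alpha = (-1 + sign * sqrt(5)) / 2`, the scalar used to build
#' star algebras over the quadratic field; both signs satisfy
#' `alpha + alpha^2 = 1` exactly, and the two roots multiply to -1.
#'
#' @param sign `+1` (default) or `-1`, selecting the root.
#' @return A `laa_scalar` in `field_quadratic(5)`.
#' @export
#' @examples
#' a <- golden_alpha()
#' a + a * a        # 1
golden_alpha <- function(sign = 1) {
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1", call. = FALSE)
  f <- field_quadratic(5)
  .sc(f, c(-1, sign), c(2, 2))
}

#' Enumerate all elements of a finite field
#'
#' @param f A finite `laa_field` with at most 4096 elements.
#' @return A list of `laa_scalar`s, starting with 0.
#' @export
field_elements <- function(f) {
  if (f$kind != "finite") stop("field_elements requires a finite field", call. = FALSE)
  q <- .field_card(f)
  if (q > 4096) stop("field too large to enumerate (", q, " elements)", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(0:(f$p - 1)), f$k)))
  lapply(seq_len(q), function(i) .sc(f, as.numeric(grid[i, ])))
}

## ---- generic scalar coercion ----

.parse_fraction <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  if (!grepl("^-?[0-9]+(/-?[0-9]+)?$", s))
    stop("cannot parse '", s, "' as an exact fraction (expected e.g. \"3/4\")",
         call. = FALSE)
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  num <- as.numeric(parts[1])
  den <- if (length(parts) == 2) as.numeric(parts[2]) else 1
  c(num, den)
}

#' Coerce a value into an exact scalar of a field
#'
#' Accepts an existing scalar of the same field, a whole number, a fraction
#' string such as `"3/4"`, a list `list(a = "1/2", b = "-1/2")` for a
#' quadratic field element `a + b*sqrt(d)`, or an integer coefficient vector
#' for a finite-field element (ascending powers of the generator).
#'
#' @param f A `laa_field`.
#' @param x The value to coerce.
#' @return A canonical `laa_scalar`.
#' @export
#' @examples
#' scalar(field_rational(), "2/4")    # canonicalised to 1/2
scalar <- function(f, x) {
  if (inherits(x, "laa_scalar")) {
    if (!.field_eq(x$f, f))
      stop("scalar belongs to a different field (", format(x$f), ")", call. = FALSE)
    return(x)
  }
  if (is.character(x) && length(x) == 1) {
    r <- .parse_fraction(x)
    return(sc_rat(f, r[1], r[2]))
  }
  if (is.list(x) && all(c("a", "b") %in% names(x))) {
    if (f$kind != "quadratic")
      stop("pair {a, b} notation is only valid for quadratic fields", call. = FALSE)
    ra <- if (is.character(x$a)) .parse_fraction(x$a) else c(as.numeric(x$a), 1)
    rb <- if (is.character(x$b)) .parse_fraction(x$b) else c(as.numeric(x$b), 1)
    na <- .rat_norm(ra[1], ra[2]); nb <- .rat_norm(rb[1], rb[2])
    return(.sc(f, c(na$num, nb$num), c(na$den, nb$den)))
  }
  if (is.numeric(x)) {
    if (f$kind == "finite" && length(x) == f$k && all(x == round(x)))
      return(.sc(f, as.numeric(x) %% f$p))
    if (length(x) == 1 && x == round(x))
      return(sc_int(f, x))
  }
  stop("cannot coerce ", deparse(substitute(x)), " to a scalar of ",
       format(f), call. = FALSE)
}

## ---- formatting and operator sugar ----

.rat_format <- function(num, den) {
  if (den == 1) as.character(num) else paste0(num, "/", den)
}

#' @export
format.laa_scalar <- function(x, ...) {
  f <- x$f
  switch(f$kind,
    rational = .rat_format(x$num, x$den),
    quadratic = {
      a <- .rat_format(x$num[1], x$den[1])
      if (x$num[2] == 0) return(a)
      b <- .rat_format(abs(x$num[2]), x$den[2])
      sgn <- if (x$num[2] < 0) " - " else " + "
      core <- paste0(if (b == "1") "" else paste0(b, "*"), "sqrt(", f$d, ")")
      if (x$num[1] == 0) {
        paste0(if (x$num[2] < 0) "-" else "", core)
      } else {
        paste0(a, sgn, core)
      }
    },
    finite = .pp_format(x$num, "t"))
}

#' @export
print.laa_scalar <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.laa_scalar <- function(x, ...) format(x)

#' @export
as.double.laa_scalar <- function(x, ...) {
  f <- x$f
  switch(f$kind,
    rational  = x$num / x$den,
    quadratic = x$num[1] / x$den[1] + (x$num[2] / x$den[2]) * sqrt(f$d),
    finite    = stop("finite-field elements have no numeric value", call. = FALSE))
}

#' Arithmetic and comparison for exact scalars
#'
#' `+`, `-`, `*`, `/`, `^`, `==`, `!=` work on pairs of scalars of the same
#' field (whole-number operands are embedded automatically); order
#' comparisons work on ordered fields only.
#'
#' @param e1,e2 Scalars or whole numbers.
#' @return A scalar or logical.
#' @export
Ops.laa_scalar <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(sc_neg(e1))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for scalars", call. = FALSE)
  }
  if (.Generic == "^") {
    if (!is.numeric(e2) || e2 != round(e2))
      stop("scalar powers must be whole numbers", call. = FALSE)
    return(sc_pow(e1, e2))
  }
  if (!inherits(e1, "laa_scalar")) e1 <- scalar(e2$f, e1)
  if (!inherits(e2, "laa_scalar")) e2 <- scalar(e1$f, e2)
  switch(.Generic,
    "+" = sc_add(e1, e2),
    "-" = sc_sub(e1, e2),
    "*" = sc_mul(e1, e2),
    "/" = sc_div(e1, e2),
    "==" = sc_eq(e1, e2),
    "!=" = !sc_eq(e1, e2),
    "<"  = sc_sign(sc_sub(e1, e2)) < 0,
    ">"  = sc_sign(sc_sub(e1, e2)) > 0,
    "<=" = sc_sign(sc_sub(e1, e2)) <= 0,
    ">=" = sc_sign(sc_sub(e1, e2)) >= 0,
    stop(.Generic, " not defined for scalars", call. = FALSE))
}
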