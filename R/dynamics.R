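# Population equilibria and random-mating dynamics.  Idempotents x = x^2
# are the fixed points of the squaring map (a population mating with
# itself); they are found exactly: by elimination for small symbolic
# systems, by element enumeration over finite fields, or by a numeric grid
# scan whose hits are rationalised and then verified exactly.

## ---- exact univariate polynomials (ascending lists of scalars) ----

.up_trim <- function(p) {
  while (length(p) > 1 && sc_is_zero(p[[length(p)]])) p[[length(p)]] <- NULL
  p
}

.up_zero <- function(f) list(sc_zero(f))
.up_is_zero <- function(p) all(vapply(p, sc_is_zero, logical(1)))
.up_deg <- function(p) length(.up_trim(p)) - 1L

.up_add <- function(f, a, b) {
  ln <- max(length(a), length(b))
  out <- vector("list", ln)
  for (i in seq_len(ln)) {
    ai <- if (i <= length(a)) a[[i]] else sc_zero(f)
    bi <- if (i <= length(b)) b[[i]] else sc_zero(f)
    out[[i]] <- sc_add(ai, bi)
  }
  .up_trim(out)
}

.up_neg <- function(p) lapply(p, sc_neg)
.up_sub <- function(f, a, b) .up_add(f, a, .up_neg(b))

.up_mul <- function(f, a, b) {
  if (.up_is_zero(a) || .up_is_zero(b)) return(.up_zero(f))
  out <- vector("list", length(a) + length(b) - 1L)
  for (i in seq_along(out)) out[[i]] <- sc_zero(f)
  for (i in seq_along(a)) {
    if (sc_is_zero(a[[i]])) next
    for (j in seq_along(b)) {
      if (sc_is_zero(b[[j]])) next
      out[[i + j - 1L]] <- sc_add(out[[i + j - 1L]], sc_mul(a[[i]], b[[j]]))
    }
  }
  .up_trim(out)
}

.up_eval <- function(f, p, x) {
  acc <- sc_zero(f)
  for (i in rev(seq_along(p))) acc <- sc_add(sc_mul(acc, x), p[[i]])
  acc
}

.up_scale <- function(c, p) lapply(p, function(v) sc_mul(c, v))

.up_format <- function(p, var = "u") {
  p <- .up_trim(p)
  if (.up_is_zero(p)) return("0")
  terms <- character(0)
  for (i in seq_along(p)) {
    if (sc_is_zero(p[[i]])) next
    pw <- i - 1L
    cs <- format(p[[i]])
    terms <- c(terms,
               if (pw == 0) cs
               else if (pw == 1) paste0("(", cs, ")*", var)
               else paste0("(", cs, ")*", var, "^", pw))
  }
  paste(terms, collapse = " + ")
}

# synthetic division by (u - r); caller guarantees r is a root
.up_deflate <- function(f, p, r) {
  p <- .up_trim(p)
  d <- length(p) - 1L
  out <- vector("list", d)
  acc <- p[[d + 1L]]
  for (i in d:1) {
    out[[i]] <- acc
    acc <- sc_add(p[[i]], sc_mul(acc, r))
  }
  .up_trim(out)
}

# determinant of a small square matrix of polynomials (Laplace expansion)
.up_det <- function(f, M) {
  n <- nrow(M)
  if (n == 1) return(M[[1, 1]])
  acc <- .up_zero(f)
  sgn <- 1
  for (j in seq_len(n)) {
    if (!.up_is_zero(M[[1, j]])) {
      sub <- M[-1, -j, drop = FALSE]
      term <- .up_mul(f, M[[1, j]], .up_det(f, sub))
      acc <- if (sgn > 0) .up_add(f, acc, term) else .up_sub(f, acc, term)
    }
    sgn <- -sgn
  }
  acc
}

# Sylvester resultant of polynomials a(u), b(u) whose coefficients are
# themselves polynomials in v (lists of upolys, ascending in u)
.up_resultant <- function(f, a, b) {
  trim_b <- function(p) { # trim in u
    while (length(p) > 1 && .up_is_zero(p[[length(p)]])) p[[length(p)]] <- NULL
    p
  }
  a <- trim_b(a); b <- trim_b(b)
  m <- length(a) - 1L; n <- length(b) - 1L
  if (m < 1 || n < 1) {
    # constant in u: resultant is that constant (to a power); good enough
    cst <- if (m < 1) a[[1]] else b[[1]]
    return(cst)
  }
  size <- m + n
  M <- vector("list", size * size); dim(M) <- c(size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) M[[i, j]] <- .up_zero(f)
  for (r in seq_len(n))    # n rows of a's coefficients (descending)
    for (t in 0:m) M[[r, r + t]] <- a[[m + 1L - t]]
  for (r in seq_len(m))    # m rows of b's coefficients
    for (t in 0:n) M[[n + r, r + t]] <- b[[n + 1L - t]]
  .up_det(f, M)
}

## ---- exact root finding ----

# all roots of a quadratic/linear A u^2 + B u + C within the field
.solve_deg2 <- function(f, A, B, C) {
  if (sc_is_zero(A)) {
    if (sc_is_zero(B)) return(list())        # constant: no roots (C != 0)
    return(list(sc_neg(sc_div(C, B))))
  }
  disc <- sc_sub(sc_mul(B, B), sc_mul(sc_rat(f, 4, 1), sc_mul(A, C)))
  rt <- sc_sqrt(disc)
  if (is.null(rt)) return(list())
  twoA <- sc_mul(sc_rat(f, 2, 1), A)
  r1 <- sc_div(sc_sub(rt, B), twoA)
  r2 <- sc_div(sc_sub(sc_neg(rt), B), twoA)
  if (sc_eq(r1, r2)) list(r1) else list(r1, r2)
}

.divisors <- function(n) {
  n <- abs(n)
  if (n == 0) return(1)
  out <- c()
  d <- 1
  while (d * d <= n) {
    if (n %% d == 0) out <- c(out, d, n / d)
    d <- d + 1
  }
  sort(unique(out))
}

# roots of an exact-coefficient polynomial within the field; handles any
# degree <= 2 directly, and higher degrees when coefficients are rational
# (rational-root search plus deflation, finishing any quadratic remainder)
.up_roots <- function(f, p) {
  p <- .up_trim(p)
  if (.up_is_zero(p)) stop("zero polynomial has every root", call. = FALSE)
  roots <- list()
  # strip root at 0
  while (length(p) > 1 && sc_is_zero(p[[1]])) {
    roots <- c(roots, list(sc_zero(f)))
    p <- p[-1]
  }
  deg <- length(p) - 1L
  if (deg == 0) return(roots)
  if (deg <= 2) {
    A <- if (deg == 2) p[[3]] else sc_zero(f)
    B <- if (deg >= 1) p[[2]] else sc_zero(f)
    return(c(roots, .solve_deg2(f, A, B, p[[1]])))
  }
  # need rational coefficients for the rational-root search
  rat_of <- function(s) {
    if (f$kind == "rational") return(c(s$num, s$den))
    if (f$kind == "quadratic" && s$num[2] == 0) return(c(s$num[1], s$den[1]))
    NULL
  }
  coeffs <- lapply(p, rat_of)
  if (any(vapply(coeffs, is.null, logical(1))))
    return(c(roots, list()))   # give up beyond degree 2 with surd coefficients
  dens <- vapply(coeffs, function(c) c[2], numeric(1))
  L <- Reduce(function(a, b) a / .laa_gcd1(a, b) * b, dens)
  ints <- vapply(coeffs, function(c) c[1] * (L / c[2]), numeric(1))
  .laa_chk_int(ints)
  a0 <- ints[1]; al <- ints[length(ints)]
  cand_p <- .divisors(a0); cand_q <- .divisors(al)
  for (pp in cand_p) for (qq in cand_q) for (sgn in c(1, -1)) {
    r <- sc_rat(f, sgn * pp, qq)
    if (sc_is_zero(.up_eval(f, p, r))) {
      roots <- c(roots, list(r))
      p <- .up_deflate(f, p, r)
      return(c(roots, .up_roots(f, p)))    # recurse on the deflated poly
    }
  }
  # no rational root; a quadratic remainder could still split in Q(sqrt d)
  if (length(p) - 1L == 2L)
    return(c(roots, .solve_deg2(f, p[[3]], p[[2]], p[[1]])))
  c(roots, list())
}

## ---- residual of the squaring map and its polynomial form ----

# x(u): the element parameterised by free coordinates u (weight-1 uses
# x_n = 1 - sum u_i); returns laa_element
.param_element <- function(A, u, weight1) {
  f <- A$field
  n <- A$n
  if (weight1) {
    s <- sc_zero(f)
    for (c in u) s <- sc_add(s, c)
    cf <- c(u, list(sc_sub(sc_one(f), s)))
  } else cf <- u
  structure(list(f = f, coeffs = cf), class = "laa_element")
}

.residual <- function(A, x) el_sub(multiply(A, x, x), x)

# interpolate coordinate c of the residual as an exact polynomial:
#   m = 1: quadratic in u        (returns upoly)
#   m = 2: quadratic in (u, v)   (returns list of upolys in v, ascending in u)
.residual_poly1 <- function(A, weight1, coord) {
  f <- A$field
  ev <- function(uval) {
    x <- .param_element(A, list(sc_int(f, uval)), weight1)
    .residual(A, x)$coeffs[[coord]]
  }
  f0 <- ev(0); f1 <- ev(1); f2 <- ev(2)
  # f(u) = c0 + c1 u + c2 u^2 through (0,1,2)
  c2 <- sc_div(sc_add(sc_sub(f2, sc_mul(sc_rat(f, 2, 1), f1)), f0),
               sc_rat(f, 2, 1))
  c1 <- sc_sub(sc_sub(f1, f0), c2)
  .up_trim(list(f0, c1, c2))
}

.residual_poly2 <- function(A, weight1, coord) {
  f <- A$field
  ev <- function(uu, vv) {
    x <- .param_element(A, list(sc_int(f, uu), sc_int(f, vv)), weight1)
    .residual(A, x)$coeffs[[coord]]
  }
  two <- sc_rat(f, 2, 1)
  g <- function(a, b) ev(a, b)
  # univariate fits along the axes
  c00 <- g(0, 0)
  cu2 <- sc_div(sc_add(sc_sub(g(2, 0), sc_mul(two, g(1, 0))), c00), two)
  cu1 <- sc_sub(sc_sub(g(1, 0), c00), cu2)
  cv2 <- sc_div(sc_add(sc_sub(g(0, 2), sc_mul(two, g(0, 1))), c00), two)
  cv1 <- sc_sub(sc_sub(g(0, 1), c00), cv2)
  cuv <- sc_sub(g(1, 1),
                sc_add(sc_add(c00, sc_add(cu1, cu2)), sc_add(cv1, cv2)))
  # sanity: a total-degree-2 surface must also match (2,1), (1,2), (2,2)
  pred <- function(uu, vv) {
    uS <- sc_int(f, uu); vS <- sc_int(f, vv)
    acc <- c00
    acc <- sc_add(acc, sc_mul(cu1, uS))
    acc <- sc_add(acc, sc_mul(cu2, sc_mul(uS, uS)))
    acc <- sc_add(acc, sc_mul(cv1, vS))
    acc <- sc_add(acc, sc_mul(cv2, sc_mul(vS, vS)))
    sc_add(acc, sc_mul(cuv, sc_mul(uS, vS)))
  }
  for (pt in list(c(2, 1), c(1, 2), c(2, 2))) {
    if (!sc_eq(pred(pt[1], pt[2]), g(pt[1], pt[2])))
      stop("internal: residual is not quadratic")   # cannot happen
  }
  # ascending in u: [C(v), B(v), A] with C = c00 + cv1 v + cv2 v^2, etc.
  list(.up_trim(list(c00, cv1, cv2)),
       .up_trim(list(cu1, cuv)),
       .up_trim(list(cu2)))
}

.biv_format <- function(f, P) {
  parts <- character(0)
  for (i in seq_along(P)) {
    if (.up_is_zero(P[[i]])) next
    c <- .up_format(P[[i]], "v")
    parts <- c(parts, if (i == 1) c
               else if (i == 2) paste0("(", c, ")*u")
               else paste0("(", c, ")*u^", i - 1))
  }
  if (length(parts) == 0) "0" else paste(parts, collapse = " + ")
}

.biv_eval_v <- function(f, P, v) {
  # substitute v, leaving a univariate polynomial in u
  .up_trim(lapply(P, function(cv) .up_eval(f, cv, v)))
}

## ---- the public operations ----

.equilibria <- function(kind, points, constraints, method, weight1) {
  structure(list(kind = kind, points = points, constraints = constraints,
                 method = method, weight1 = weight1),
            class = "laa_equilibria")
}

#' @export
print.laa_equilibria <- function(x, ...) {
  cat(sprintf("<equilibria> kind: %s (%d point%s, method %s%s)\n",
              x$kind, length(x$points),
              if (length(x$points) == 1) "" else "s", x$method,
              if (x$weight1) ", weight-1" else ""))
  if (length(x$constraints) > 0)
    cat("  constraints:", paste(x$constraints, collapse = "; "), "\n")
  for (p in utils::head(x$points, 6)) cat("  ", format(p), "\n")
  if (length(x$points) > 6) cat("  ... (", length(x$points) - 6, " more)\n")
  invisible(x)
}

#' Find the idempotent elements of an algebra
#'
#' Idempotents `x = x^2` are the equilibria of random mating: a population
#' whose offspring distribution equals itself.  Over finite fields the
#' search is by exhaustive enumeration.  Over ordered fields the symbolic
#' method first tests whether the whole weight-1 set is idempotent (true
#' for Mendelian gametic and star algebras), reporting a continuum; else it
#' solves the quadratic system exactly — directly for one free coordinate,
#' by resultant elimination for two.  A positive-dimensional solution
#' variety (e.g. the Hardy-Weinberg curve of a zygotic algebra) is reported
#' as a continuum with its defining polynomial constraints and a few exact
#' sample points.  The numeric `grid` method scans a float grid, refines,
#' rationalises, and keeps only points that verify `x^2 = x` exactly.
#'
#' @param A A `laa_algebra`.
#' @param weight1 Restrict to coefficient-sum-1 (population) elements.
#' @param method `"symbolic"` (default; needs at most 2 free coordinates,
#'   i.e. `n <= 3` with `weight1 = TRUE`) or `"grid"`.
#' @param grid_points Per-coordinate resolution of the grid method.
#' @return A `laa_equilibria` object; every returned point satisfies
#'   `x^2 = x` with zero residual.
#' @export
#' @examples
#' Mu <- mutation_algebra("1/4", "1/2")
#' find_idempotents(Mu)                # unique equilibrium (2/3, 1/3)
find_idempotents <- function(A, weight1 = TRUE,
                             method = c("symbolic", "grid"),
                             grid_points = 11) {
  method <- match.arg(method)
  f <- A$field
  n <- A$n
  if (f$kind == "finite") {
    if (.field_card(f)^n > 1e5)
      stop("finite-field search space too large", call. = FALSE)
    els <- field_elements(f)
    pts <- list()
    .tuple_scan(length(els), n, function(idx) {
      x <- structure(list(f = f, coeffs = els[idx]), class = "laa_element")
      if (weight1 && !sc_is_one(weight(x))) return(NULL)
      if (el_eq(multiply(A, x, x), x)) pts[[length(pts) + 1L]] <<- x
      NULL
    })
    return(.equilibria(if (length(pts) > 0) "isolated" else "none-found",
                       pts, character(0), "element-exhaustive", weight1))
  }
  m <- n - as.integer(weight1)
  if (m == 0) {
    x <- .param_element(A, list(), TRUE)
    ok <- el_is_zero(.residual(A, x))
    return(.equilibria(if (ok) "isolated" else "none-found",
                       if (ok) list(x) else list(), character(0),
                       "symbolic", weight1))
  }
  if (method == "grid") return(.idem_grid(A, weight1, grid_points))

  # continuum pre-check: does the residual vanish identically?  (valid in
  # any dimension: a quadratic vanishing on a {0,1,2}^m grid is zero)
  grid_ident <- if (m <= 7) .tuple_scan(3L, m, function(idx) {
    u <- lapply(idx - 1L, function(v) sc_int(f, v))
    if (el_is_zero(.residual(A, .param_element(A, u, weight1)))) NULL else TRUE
  }) else TRUE
  if (is.null(grid_ident)) {
    # quadratic residual vanishing on a {0,1,2}^m grid is identically zero
    pts <- lapply(list(rep(0, m),
                       c(1, rep(0, m - 1)),
                       rep(list("1/2"), m)[seq_len(m)]),
                  function(u) .param_element(
                    A, lapply(u, function(v) scalar(f, v)), weight1))
    pts <- Filter(function(x) el_is_zero(.residual(A, x)), pts)
    cons <- if (weight1) "x1 + ... + xn = 1 (the entire weight-1 set)"
            else "no constraint (every element idempotent)"
    return(.equilibria("continuum", pts, cons, "symbolic", weight1))
  }
  if (m > 2)
    stop("the symbolic method handles at most 2 free coordinates (n <= 3 ",
         "with weight1 = TRUE) unless the whole weight-1 set is idempotent; ",
         "use method = \"grid\"", call. = FALSE)

  if (m == 1) {
    polys <- lapply(seq_len(n), function(c) .residual_poly1(A, weight1, c))
    polys <- Filter(Negate(.up_is_zero), polys)
    roots <- .up_roots(f, polys[[1]])
    roots <- Filter(function(r)
      all(vapply(polys, function(p) sc_is_zero(.up_eval(f, p, r)), logical(1))),
      roots)
    pts <- lapply(roots, function(r) .param_element(A, list(r), weight1))
    pts <- Filter(function(x) el_is_zero(.residual(A, x)), pts)   # defensive
    return(.equilibria(if (length(pts) > 0) "isolated" else "none-found",
                       pts, character(0), "symbolic", weight1))
  }

  # m == 2: bivariate quadratics; eliminate u by resultant
  polys <- lapply(seq_len(n), function(c) .residual_poly2(A, weight1, c))
  nonzero <- Filter(function(P) !all(vapply(P, .up_is_zero, logical(1))), polys)
  cons <- vapply(nonzero, function(P) paste0(.biv_format(f, P), " = 0"),
                 character(1))
  verify <- function(x) el_is_zero(.residual(A, x))
  solve_on_line <- function(v) {
    # all idempotents with second free coordinate exactly v
    cands <- list()
    for (P in nonzero) {
      pu <- .biv_eval_v(f, P, v)
      if (.up_is_zero(pu)) next
      cands <- .up_roots(f, pu)
      break
    }
    out <- list()
    for (u in cands) {
      x <- .param_element(A, list(u, v), weight1)
      if (verify(x)) out[[length(out) + 1L]] <- x
    }
    out
  }
  if (length(nonzero) >= 2) {
    res <- .up_resultant(f, nonzero[[1]], nonzero[[2]])
  } else res <- .up_zero(f)
  if (.up_is_zero(res)) {
    # common positive-dimensional component: sample it
    pts <- list()
    for (vv in c("0", "1", "1/2", "1/4", "3/4", "-1", "2", "1/3")) {
      for (x in solve_on_line(scalar(f, vv))) {
        if (!any(vapply(pts, function(p) el_eq(p, x), logical(1))))
          pts[[length(pts) + 1L]] <- x
      }
      if (length(pts) >= 3) break
    }
    return(.equilibria("continuum", pts, cons, "symbolic", weight1))
  }
  vroots <- .up_roots(f, res)
  pts <- list()
  for (v in vroots) {
    for (x in solve_on_line(v)) {
      if (!any(vapply(pts, function(p) el_eq(p, x), logical(1))))
        pts[[length(pts) + 1L]] <- x
    }
  }
  .equilibria(if (length(pts) > 0) "isolated" else "none-found",
              pts, character(0), "symbolic", weight1)
}

# numeric grid scan: iterate the squaring map in floating point from each
# grid start (so attracting equilibria are reached), rationalise the limit
# by continued fractions, and keep only points that verify x^2 = x exactly
.idem_grid <- function(A, weight1, grid_points) {
  f <- A$field
  n <- A$n
  m <- n - as.integer(weight1)
  vals <- seq(0, 1, length.out = grid_points)
  gnum <- array(0, dim = c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    gnum[i, j, k] <- as.double.laa_scalar(A$tensor$gamma[[i, j, k]])
  sq_num <- function(x) {
    out <- numeric(n)
    for (k in seq_len(n)) out[k] <- sum(outer(x, x) * gnum[, , k])
    out
  }
  rationalise <- function(x, maxden = 512) {
    best <- c(round(x), 1)
    for (q in 1:maxden) {
      p <- round(x * q)
      if (abs(p / q - x) < abs(best[1] / best[2] - x) - 1e-15) best <- c(p, q)
      if (abs(best[1] / best[2] - x) < 1e-12) break
    }
    best
  }
  pts <- list()
  .tuple_scan(grid_points, m, function(idx) {
    u_num <- vals[idx]
    x_num <- if (weight1) c(u_num, 1 - sum(u_num)) else u_num
    for (it in 1:60) {
      nx <- sq_num(x_num)
      if (any(!is.finite(nx)) || max(abs(nx)) > 1e6) return(NULL)
      if (max(abs(nx - x_num)) < 1e-13) { x_num <- nx; break }
      x_num <- nx
    }
    cf <- lapply(x_num, function(v) {
      r <- rationalise(v)
      sc_rat(f, r[1], r[2])
    })
    x <- structure(list(f = f, coeffs = cf), class = "laa_element")
    if (weight1) {
      s <- sc_zero(f)
      for (i in seq_len(n - 1)) s <- sc_add(s, x$coeffs[[i]])
      x$coeffs[[n]] <- sc_sub(sc_one(f), s)
    }
    if (el_is_zero(.residual(A, x)) &&
        !any(vapply(pts, function(p) el_eq(p, x), logical(1))))
      pts[[length(pts) + 1L]] <<- x
    NULL
  })
  .equilibria(if (length(pts) > 0) "isolated" else "none-found",
              pts, character(0), "grid+verify", weight1)
}

#' Iterate the random-mating squaring map
#'
#' Starting from `x0`, computes `x_{g+1} = x_g^2` for the requested number
#' of generations, exactly.  On ordered fields the trajectory is flagged
#' converged when successive iterates differ by less than `tol` in every
#' coordinate (the iterates themselves remain exact).
#'
#' @param A A `laa_algebra`.
#' @param x0 Starting element (coerced via [element()]).
#' @param generations Number of squaring steps (`>= 1`).
#' @param tol Convergence tolerance for the flag only.
#' @return A `laa_trajectory`: list with `iterates` (length
#'   `generations + 1`), `converged`, and `limit` (the last iterate).
#' @export
#' @examples
#' Mu <- mutation_algebra("1/4", "1/2")
#' tr <- evolve(Mu, basis_element(Mu, 1), generations = 8)
#' format(tr$limit)
evolve <- function(A, x0, generations, tol = 1e-9) {
  generations <- as.integer(generations)
  if (generations < 1) stop("need at least one generation", call. = FALSE)
  x <- element(A, x0)
  iterates <- vector("list", generations + 1L)
  iterates[[1]] <- x
  converged <- FALSE
  for (g in seq_len(generations)) {
    nx <- multiply(A, x, x)
    iterates[[g + 1L]] <- nx
    if (.field_ordered(A$field)) {
      dmax <- max(abs(as.numeric(nx) - as.numeric(x)))
      if (dmax < tol) converged <- TRUE
    }
    x <- nx
  }
  structure(list(iterates = iterates, converged = converged,
                 limit = iterates[[generations + 1L]],
                 basis = A$basis),
            class = "laa_trajectory")
}

#' @export
print.laa_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d generations, converged: %s\n",
              length(x$iterates) - 1L, x$converged))
  cat("  limit:", format(x$limit), "\n")
  invisible(x)
}

#' @export
as.data.frame.laa_trajectory <- function(x, ...) {
  num <- t(vapply(x$iterates, as.numeric, numeric(length(x$basis))))
  df <- data.frame(generation = seq_len(nrow(num)) - 1L, num)
  names(df)[-1] <- x$basis
  df
}

#' Max-norm distance from an element to an equilibrium set
#'
#' For isolated equilibria: the exact minimum over points of the largest
#' absolute coordinate difference.  For the full weight-1 continuum: the
#' exact distance `|weight(x) - 1| / n` to the weight-1 affine set.  For a
#' polynomial continuum the minimum over the stored sample points is
#' returned (an upper bound on the true distance).
#'
#' @param x A `laa_element` over an ordered field.
#' @param E A `laa_equilibria` object.
#' @return An exact nonnegative `laa_scalar`.
#' @export
distance_to_set <- function(x, E) {
  f <- x$f
  if (!.field_ordered(f))
    stop("distance is only defined over ordered fields", call. = FALSE)
  el_dist <- function(p) {
    d <- sc_zero(f)
    for (i in seq_along(x$coeffs)) {
      di <- sc_abs(sc_sub(x$coeffs[[i]], p$coeffs[[i]]))
      if (sc_sign(sc_sub(di, d)) > 0) d <- di
    }
    d
  }
  if (E$kind == "continuum" && length(E$constraints) == 1 &&
      grepl("weight-1 set", E$constraints[1])) {
    dev <- sc_abs(sc_sub(weight(x), sc_one(f)))
    return(sc_div(dev, sc_int(f, length(x$coeffs))))
  }
  if (length(E$points) == 0)
    stop("equilibrium set has no points to measure against", call. = FALSE)
  best <- el_dist(E$points[[1]])
  for (p in E$points[-1]) {
    d <- el_dist(p)
    if (sc_sign(sc_sub(d, best)) < 0) best <- d
  }
  best
}
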