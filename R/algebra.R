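# Finite-dimensional algebras given by a structure-constant tensor
# gamma[i, j, k]: the bilinear product of basis elements is
# a_i a_j = sum_k gamma[i, j, k] a_k.  All indices are 1-based in every
# user-facing message, matching the usual subscript convention.

## ---- structure tensors ----

#' Build a structure-constant tensor
#'
#' @param field The `laa_field` the entries live in.
#' @param entries Either a list with `dim = c(n, n, n)` of scalars (or values
#'   coercible by [scalar()]), or a character/numeric array of the same shape.
#' @return A `laa_tensor`: a list with fields `n` and `gamma` (a list-array
#'   of canonical scalars).
#' @export
structure_tensor <- function(field, entries) {
  d <- dim(entries)
  if (is.null(d) || length(d) != 3 || d[1] != d[2] || d[2] != d[3])
    stop("tensor entries must be an n x n x n array", call. = FALSE)
  n <- d[1]
  gamma <- vector("list", n^3)
  dim(gamma) <- c(n, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    v <- if (is.list(entries)) entries[[i, j, k]] else entries[i, j, k]
    gamma[[i, j, k]] <- scalar(field, v)
  }
  structure(list(n = n, gamma = gamma), class = "laa_tensor")
}

# row sum over k for pair (i, j)
.tensor_row_sum <- function(field, tensor, i, j) {
  s <- sc_zero(field)
  for (k in seq_len(tensor$n)) s <- sc_add(s, tensor$gamma[[i, j, k]])
  s
}

#' Validate structure-constant tensor properties
#'
#' Checks the gametic constraints: every row sum `sum_k gamma[i,j,k] = 1`
#' (`row_stochastic`), all entries within `[0, 1]` on ordered fields
#' (`bounded`), and the symmetry `gamma[i,j,k] = gamma[j,i,k]`
#' (`symmetric`).  Violations are reported with the offending indices.
#'
#' @param field The tensor's field.
#' @param tensor A `laa_tensor`.
#' @param checks Character vector among `"row_stochastic"`, `"bounded"`,
#'   `"symmetric"`.
#' @return Invisibly `TRUE`; errors describe every violated constraint.
#' @export
validate_tensor <- function(field, tensor,
                            checks = c("row_stochastic", "bounded", "symmetric")) {
  n <- tensor$n
  problems <- character(0)
  one <- sc_one(field); zero <- sc_zero(field)
  if ("row_stochastic" %in% checks) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- .tensor_row_sum(field, tensor, i, j)
      if (!sc_eq(s, one))
        problems <- c(problems, sprintf(
          "row sum for (i=%d, j=%d) is %s, not 1", i, j, format(s)))
    }
  }
  if ("bounded" %in% checks && .field_ordered(field)) {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      g <- tensor$gamma[[i, j, k]]
      if (sc_sign(g) < 0 || sc_sign(sc_sub(g, one)) > 0)
        problems <- c(problems, sprintf(
          "entry gamma[%d,%d,%d] = %s lies outside [0, 1]", i, j, k, format(g)))
    }
  }
  if ("symmetric" %in% checks) {
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
      for (k in seq_len(n)) {
        if (!sc_eq(tensor$gamma[[i, j, k]], tensor$gamma[[j, i, k]]))
          problems <- c(problems, sprintf(
            "symmetry gamma[%d,%d,%d] = gamma[%d,%d,%d] violated: %s vs %s",
            i, j, k, j, i, k,
            format(tensor$gamma[[i, j, k]]), format(tensor$gamma[[j, i, k]])))
      }
  }
  if (length(problems) > 0)
    stop("tensor validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

## ---- algebras ----

#' Assemble an algebra from a field, basis labels and a tensor
#'
#' @param field A `laa_field`.
#' @param basis Character vector of unique basis labels, e.g. `c("a1","a2")`.
#' @param tensor A `laa_tensor` of matching dimension (or raw entries passed
#'   to [structure_tensor()]).
#' @param provenance Free-form list recording how the algebra was built.
#' @return A `laa_algebra`.
#' @export
algebra <- function(field, basis, tensor, provenance = list()) {
  if (!inherits(tensor, "laa_tensor")) tensor <- structure_tensor(field, tensor)
  basis <- as.character(basis)
  if (length(basis) != tensor$n) stop("basis has ", length(basis),
                                      " labels but tensor dimension is ",
                                      tensor$n, call. = FALSE)
  if (anyDuplicated(basis)) stop("basis labels must be unique", call. = FALSE)
  structure(list(field = field, basis = basis, n = tensor$n,
                 tensor = tensor, provenance = provenance),
            class = "laa_algebra")
}

#' @export
print.laa_algebra <- function(x, ...) {
  cat(sprintf("<laa_algebra> dim %d over %s\n", x$n, format(x$field)))
  cat("  basis:", paste(x$basis, collapse = ", "), "\n")
  if (!is.null(x$provenance$constructor))
    cat("  constructor:", x$provenance$constructor, "\n")
  invisible(x)
}

#' @export
dim.laa_algebra <- function(x) x$n

## ---- elements ----

#' Build an element of an algebra from coefficients
#'
#' @param A A `laa_algebra`.
#' @param coeffs A list of scalars / fraction strings / whole numbers of
#'   length `dim(A)` — the coordinates over the basis.
#' @return A `laa_element`.
#' @export
#' @examples
#' G <- mendelian_gametic(2)
#' x <- element(G, c("1/2", "1/2"))
#' weight(x)
element <- function(A, coeffs) {
  if (inherits(coeffs, "laa_element")) {
    if (length(coeffs$coeffs) != A$n)
      stop("element has length ", length(coeffs$coeffs),
           " but the algebra has dimension ", A$n, call. = FALSE)
    return(coeffs)
  }
  if (length(coeffs) != A$n)
    stop("expected ", A$n, " coefficients, got ", length(coeffs), call. = FALSE)
  cf <- lapply(seq_len(A$n), function(i) {
    scalar(A$field, if (is.list(coeffs)) coeffs[[i]] else coeffs[i])
  })
  structure(list(f = A$field, coeffs = cf), class = "laa_element")
}

#' The i-th basis element of an algebra
#' @param A A `laa_algebra`.
#' @param i Basis index (1-based).
#' @return A `laa_element` with a single unit coordinate.
#' @export
basis_element <- function(A, i) {
  cf <- lapply(seq_len(A$n), function(j)
    if (j == i) sc_one(A$field) else sc_zero(A$field))
  structure(list(f = A$field, coeffs = cf), class = "laa_element")
}

el_zero <- function(A) {
  structure(list(f = A$field,
                 coeffs = lapply(seq_len(A$n), function(i) sc_zero(A$field))),
            class = "laa_element")
}

el_add <- function(x, y) {
  structure(list(f = x$f, coeffs = mapply(sc_add, x$coeffs, y$coeffs,
                                          SIMPLIFY = FALSE)),
            class = "laa_element")
}

el_sub <- function(x, y) {
  structure(list(f = x$f, coeffs = mapply(sc_sub, x$coeffs, y$coeffs,
                                          SIMPLIFY = FALSE)),
            class = "laa_element")
}

el_scale <- function(c, x) {
  structure(list(f = x$f, coeffs = lapply(x$coeffs, function(v) sc_mul(c, v))),
            class = "laa_element")
}

el_eq <- function(x, y) {
  length(x$coeffs) == length(y$coeffs) &&
    all(mapply(sc_eq, x$coeffs, y$coeffs))
}

el_is_zero <- function(x) all(vapply(x$coeffs, sc_is_zero, logical(1)))

#' @export
format.laa_element <- function(x, ...) {
  paste0("(", paste(vapply(x$coeffs, format, character(1)), collapse = ", "), ")")
}

#' @export
print.laa_element <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.double.laa_element <- function(x, ...) {
  vapply(x$coeffs, function(c) as.double.laa_scalar(c), numeric(1))
}

#' Elementwise arithmetic and comparison for algebra elements
#'
#' `+` and `-` act coordinatewise; `==` / `!=` compare exactly.  The
#' bilinear product is *not* `*` — it needs the algebra, see [multiply()].
#'
#' @param e1,e2 `laa_element`s of equal length.
#' @return An element or a logical.
#' @export
Ops.laa_element <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-")
      return(structure(list(f = e1$f, coeffs = lapply(e1$coeffs, sc_neg)),
                       class = "laa_element"))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for elements", call. = FALSE)
  }
  if (!inherits(e1, "laa_element") || !inherits(e2, "laa_element"))
    stop(.Generic, " needs two algebra elements", call. = FALSE)
  if (length(e1$coeffs) != length(e2$coeffs))
    stop("elements have different lengths", call. = FALSE)
  switch(.Generic,
    "+" = el_add(e1, e2),
    "-" = el_sub(e1, e2),
    "==" = el_eq(e1, e2),
    "!=" = !el_eq(e1, e2),
    stop(.Generic, " not defined for elements (use multiply() for the ",
         "algebra product)", call. = FALSE))
}

#' Weight of an element
#'
#' The coefficient sum — the value of the baric weight homomorphism when the
#' algebra's tensor is row-stochastic.  Weight-1 elements represent
#' populations (their coordinates are relative gene frequencies).
#'
#' @param x A `laa_element`.
#' @return A `laa_scalar`.
#' @export
weight <- function(x) {
  s <- sc_zero(x$f)
  for (c in x$coeffs) s <- sc_add(s, c)
  s
}

#' Bilinear product of two elements
#'
#' `(xy)_k = sum_i sum_j x_i y_j gamma[i,j,k]`, computed exactly.
#'
#' @param A A `laa_algebra`.
#' @param x,y Elements of `A` (coerced via [element()]).
#' @return The product as a `laa_element`.
#' @export
#' @examples
#' G <- mendelian_gametic(2)
#' multiply(G, basis_element(G, 1), basis_element(G, 2))   # (1/2, 1/2)
multiply <- function(A, x, y) {
  x <- element(A, x); y <- element(A, y)
  n <- A$n
  out <- lapply(seq_len(n), function(k) sc_zero(A$field))
  g <- A$tensor$gamma
  for (i in seq_len(n)) {
    xi <- x$coeffs[[i]]
    if (sc_is_zero(xi)) next
    for (j in seq_len(n)) {
      yj <- y$coeffs[[j]]
      if (sc_is_zero(yj)) next
      c <- sc_mul(xi, yj)
      for (k in seq_len(n)) {
        gk <- g[[i, j, k]]
        if (!sc_is_zero(gk)) out[[k]] <- sc_add(out[[k]], sc_mul(c, gk))
      }
    }
  }
  structure(list(f = A$field, coeffs = out), class = "laa_element")
}

#' Principal (left-normed) power of an element
#'
#' `x^1 = x` and `x^(m+1) = x^m * x` — repeated right multiplication by `x`,
#' the only power convention meaningful in a nonassociative algebra here.
#'
#' @param A A `laa_algebra`.
#' @param x An element of `A`.
#' @param m Positive integer exponent.
#' @return A `laa_element`.
#' @export
principal_power <- function(A, x, m) {
  m <- as.integer(m)
  if (m < 1) stop("principal power requires exponent m >= 1", call. = FALSE)
  x <- element(A, x)
  acc <- x
  if (m > 1) for (i in 2:m) acc <- multiply(A, acc, x)
  acc
}

## ---- exact linear algebra over a field ----

# matrices are lists with dim = c(r, c) of scalars
.mat_new <- function(field, r, c) {
  m <- vector("list", r * c)
  dim(m) <- c(r, c)
  for (i in seq_len(r)) for (j in seq_len(c)) m[[i, j]] <- sc_zero(field)
  m
}

.mat_from <- function(field, M) {
  if (is.list(M) && !is.null(dim(M))) {
    out <- M
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
      out[[i, j]] <- scalar(field, M[[i, j]])
    return(out)
  }
  if ((is.character(M) || is.numeric(M)) && is.matrix(M)) {
    out <- vector("list", length(M))
    dim(out) <- dim(M)
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
      out[[i, j]] <- scalar(field, M[i, j])
    return(out)
  }
  stop("cannot interpret the given matrix over ", format(field), call. = FALSE)
}

# Gauss-Jordan reduction of the augmented block [M | B]; returns list with
# rank, the reduced blocks, and pivot columns.  Exact throughout.
.mat_rref <- function(field, M, B) {
  r <- nrow(M); c <- ncol(M); cb <- ncol(B)
  piv <- integer(0)
  row <- 1L
  for (col in seq_len(c)) {
    # find pivot
    prow <- 0L
    for (i in row:r) if (i <= r && !sc_is_zero(M[[i, col]])) { prow <- i; break }
    if (prow == 0L) next
    if (prow != row) {
      for (j in seq_len(c)) { t <- M[[row, j]]; M[[row, j]] <- M[[prow, j]]; M[[prow, j]] <- t }
      for (j in seq_len(cb)) { t <- B[[row, j]]; B[[row, j]] <- B[[prow, j]]; B[[prow, j]] <- t }
    }
    pinv <- sc_inv(M[[row, col]])
    for (j in seq_len(c)) M[[row, j]] <- sc_mul(M[[row, j]], pinv)
    for (j in seq_len(cb)) B[[row, j]] <- sc_mul(B[[row, j]], pinv)
    for (i in seq_len(r)) {
      if (i == row) next
      f <- M[[i, col]]
      if (sc_is_zero(f)) next
      for (j in seq_len(c)) M[[i, j]] <- sc_sub(M[[i, j]], sc_mul(f, M[[row, j]]))
      for (j in seq_len(cb)) B[[i, j]] <- sc_sub(B[[i, j]], sc_mul(f, B[[row, j]]))
    }
    piv <- c(piv, col)
    row <- row + 1L
    if (row > r) break
  }
  list(M = M, B = B, rank = length(piv), pivots = piv)
}

# solve M x = b exactly; returns list(status = "unique"|"underdetermined"|
# "inconsistent", x = particular solution with free variables set to 0)
.lin_solve <- function(field, M, b) {
  r <- nrow(M); c <- ncol(M)
  B <- vector("list", r); dim(B) <- c(r, 1L)
  for (i in seq_len(r)) B[[i, 1]] <- scalar(field, b[[i]])
  red <- .mat_rref(field, M, B)
  # inconsistency: a zero row of M with nonzero rhs
  for (i in seq_len(r)) {
    allz <- all(vapply(seq_len(c), function(j) sc_is_zero(red$M[[i, j]]), logical(1)))
    if (allz && !sc_is_zero(red$B[[i, 1]]))
      return(list(status = "inconsistent", x = NULL))
  }
  x <- lapply(seq_len(c), function(j) sc_zero(field))
  for (ridx in seq_along(red$pivots)) x[[red$pivots[ridx]]] <- red$B[[ridx, 1]]
  list(status = if (red$rank == c) "unique" else "underdetermined", x = x)
}

.mat_inv <- function(field, M) {
  n <- nrow(M)
  if (ncol(M) != n) stop("matrix must be square", call. = FALSE)
  I <- .mat_new(field, n, n)
  for (i in seq_len(n)) I[[i, i]] <- sc_one(field)
  red <- .mat_rref(field, M, I)
  if (red$rank < n)
    stop("matrix is singular over ", format(field), call. = FALSE)
  red$B
}

## ---- change of basis ----

#' Re-express an algebra in a new basis
#'
#' The rows of `M` give the new basis vectors in old coordinates:
#' `b_i = sum_j M[i, j] a_j`.  The returned algebra carries the same
#' bilinear product expressed over the new basis; changing by `M` and then
#' by its inverse restores the original tensor exactly.
#'
#' @param A A `laa_algebra`.
#' @param M An invertible `n x n` matrix of scalars (list-matrix, or a
#'   character/numeric matrix coerced entrywise).
#' @param new_labels Labels for the new basis (defaults to `b1..bn`).
#' @return A `laa_algebra` over the same field.
#' @export
#' @examples
#' Mu <- mutation_algebra("1/4", "1/2")
#' change_of_basis(Mu, matrix(c(1, 0, 1, -1), 2, 2, byrow = TRUE),
#'                 c("a", "b"))
change_of_basis <- function(A, M, new_labels = NULL) {
  n <- A$n
  M <- .mat_from(A$field, M)
  if (nrow(M) != n || ncol(M) != n)
    stop("change-of-basis matrix must be ", n, " x ", n, call. = FALSE)
  Minv <- .mat_inv(A$field, M)   # errors if singular
  if (is.null(new_labels)) new_labels <- paste0("b", seq_len(n))
  # new basis vectors as elements in old coordinates
  newb <- lapply(seq_len(n), function(i) {
    structure(list(f = A$field,
                   coeffs = lapply(seq_len(n), function(j) M[[i, j]])),
              class = "laa_element")
  })
  gamma <- vector("list", n^3); dim(gamma) <- c(n, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- multiply(A, newb[[i]], newb[[j]])   # old coordinates
    # old basis a_r = sum_k Minv[r, k] b_k  =>  new_k = sum_r w_r Minv[r, k]
    for (k in seq_len(n)) {
      s <- sc_zero(A$field)
      for (r in seq_len(n)) s <- sc_add(s, sc_mul(w$coeffs[[r]], Minv[[r, k]]))
      gamma[[i, j, k]] <- s
    }
  }
  algebra(A$field, new_labels,
          structure(list(n = n, gamma = gamma), class = "laa_tensor"),
          provenance = list(constructor = "change_of_basis",
                            parent = A$provenance))
}

# express an element given in old coordinates in the new basis of
# change_of_basis(A, M): used internally and by tests
.el_to_new_basis <- function(field, Minv, x) {
  n <- length(x$coeffs)
  cf <- lapply(seq_len(n), function(k) {
    s <- sc_zero(field)
    for (r in seq_len(n)) s <- sc_add(s, sc_mul(x$coeffs[[r]], Minv[[r, k]]))
    s
  })
  structure(list(f = field, coeffs = cf), class = "laa_element")
}
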