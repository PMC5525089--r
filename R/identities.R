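# A catalog of polynomial identities as binary product trees, a checker
# that proves multilinear identities by exhaustive basis evaluation (sound
# by bilinearity) and tests non-multilinear ones on exact weight-1 samples
# or by full element enumeration over finite fields, and a classifier.

## ---- product trees ----

.iv <- function(name, pow = 1L) list(type = "var", name = name, pow = as.integer(pow))
.im <- function(l, r) list(type = "mul", l = l, r = r)

.tree_eval <- function(A, tree, env) {
  if (tree$type == "var") {
    x <- env[[tree$name]]
    if (tree$pow == 1L) return(x)
    return(principal_power(A, x, tree$pow))
  }
  multiply(A, .tree_eval(A, tree$l, env), .tree_eval(A, tree$r, env))
}

.tree_format <- function(tree) {
  if (tree$type == "var") {
    if (tree$pow == 1L) return(tree$name)
    return(paste0(tree$name, "^", tree$pow))
  }
  paste0("(", .tree_format(tree$l), " ", .tree_format(tree$r), ")")
}

# an identity: a named set of equations lhs = rhs over variables
.idef <- function(name, vars, equations, multilinear, weight1_only = FALSE,
                  description = "") {
  structure(list(name = name, vars = vars, arity = length(vars),
                 equations = equations, multilinear = multilinear,
                 weight1_only = weight1_only, description = description),
            class = "laa_identity")
}

.ieq <- function(lhs, rhs, label = NULL) {
  if (is.null(label)) label <- paste(.tree_format(lhs), "=", .tree_format(rhs))
  list(lhs = lhs, rhs = rhs, label = label)
}

#' The identity catalog
#'
#' Named defining identities of the classical nonassociative families
#' (commutative, associative, left invertive, flexible, alternative,
#' Jordan) together with the derived consequences that hold in a left
#' almost alternative algebra: exchange rules for squares, the medial-style
#' four-variable exchange, power associativity laws, and the generalized
#' Jordan family `(x^m y) x^n = x^m (y x^n)`.  Power identities are
#' checked at a small set of exponent instances.
#'
#' @return A named list of identity definitions.
#' @export
#' @examples
#' names(identity_catalog())
identity_catalog <- function() {
  x <- .iv("x"); y <- .iv("y"); z <- .iv("z")
  a <- .iv("a"); b <- .iv("b"); c_ <- .iv("c"); d <- .iv("d")
  x2 <- .iv("x", 2)
  pow_cases <- function(build, cases) {
    lapply(cases, function(mn) build(mn[1], mn[2]))
  }
  defs <- list(
    .idef("commutative", c("x", "y"),
          list(.ieq(.im(x, y), .im(y, x))), multilinear = TRUE,
          description = "xy = yx"),
    .idef("associative", c("x", "y", "z"),
          list(.ieq(.im(.im(x, y), z), .im(x, .im(y, z)))), multilinear = TRUE,
          description = "(xy)z = x(yz)"),
    .idef("left_invertive", c("x", "y", "z"),
          list(.ieq(.im(.im(x, y), z), .im(.im(z, y), x))), multilinear = TRUE,
          description = "(xy)z = (zy)x  (left almost algebras)"),
    .idef("left_id_consequence", c("x", "y", "z"),
          list(.ieq(.im(.im(x, y), z), .im(y, .im(x, z)))), multilinear = TRUE,
          description = "(xy)z = y(xz)  (holds in LA algebras with a left identity)"),
    .idef("flexible", c("x", "y"),
          list(.ieq(.im(.im(x, y), x), .im(x, .im(y, x)))), multilinear = FALSE,
          description = "(xy)x = x(yx)"),
    .idef("generalized_jordan", c("x", "y"),
          list(.ieq(.im(.im(x, y), x2), .im(x, .im(y, x2)))), multilinear = FALSE,
          description = "(xy)x^2 = x(yx^2)"),
    .idef("alternative_left", c("x", "y"),
          list(.ieq(.im(x, .im(x, y)), .im(.im(x, x), y))), multilinear = FALSE,
          description = "x(xy) = (xx)y"),
    .idef("alternative_right", c("x", "y"),
          list(.ieq(.im(.im(y, x), x), .im(y, .im(x, x)))), multilinear = FALSE,
          description = "(yx)x = y(xx)"),
    .idef("square_commute", c("x", "y"),
          list(.ieq(.im(x2, y), .im(y, x2))), multilinear = FALSE,
          description = "x^2 y = y x^2"),
    .idef("square_left_assoc", c("x", "y"),
          list(.ieq(.im(.im(x2, y), x), .im(x2, .im(y, x)))), multilinear = FALSE,
          description = "(x^2 y)x = x^2(yx)"),
    .idef("square_assoc", c("x", "y", "z"),
          list(.ieq(.im(.im(x2, y), z), .im(x2, .im(y, z)))), multilinear = FALSE,
          description = "(x^2 y)z = x^2(yz)"),
    .idef("square_exchange", c("x", "y", "z"),
          list(.ieq(.im(x2, .im(y, z)), .im(x2, .im(z, y)))), multilinear = FALSE,
          description = "x^2(yz) = x^2(zy)"),
    .idef("medial_exchange", c("a", "b", "c", "d"),
          list(.ieq(.im(.im(a, b), .im(c_, d)), .im(.im(d, b), .im(c_, a))),
               .ieq(.im(.im(d, b), .im(c_, a)), .im(.im(d, c_), .im(b, a))),
               .ieq(.im(.im(a, b), .im(c_, d)), .im(.im(d, c_), .im(b, a)))),
          multilinear = TRUE,
          description = "(ab)(cd) = (db)(ca) = (dc)(ba), checked pairwise"),
    .idef("power_sum", "a",
          pow_cases(function(m, n) .ieq(.im(.iv("a", m), .iv("a", n)),
                                        .iv("a", m + n)),
                    list(c(1, 2), c(2, 2), c(2, 3))),
          multilinear = FALSE,
          description = "a^m a^n = a^(m+n)"),
    .idef("power_power", "a",
          lapply(list(c(2, 2), c(2, 3), c(3, 2)), function(mn) {
            m <- mn[1]; n <- mn[2]
            # (a^m)^n as a principal power of a^m must be built by nesting
            inner <- .iv("a", m)
            acc <- inner
            if (n > 1) for (i in 2:n) acc <- .im(acc, inner)
            .ieq(acc, .iv("a", m * n),
                 label = sprintf("(a^%d)^%d = a^%d", m, n, m * n))
          }),
          multilinear = FALSE,
          description = "(a^m)^n = a^(mn)"),
    .idef("product_power", c("a", "b"),
          lapply(2:3, function(n) {
            ab <- .im(.iv("a"), .iv("b"))
            acc <- ab
            for (i in 2:n) acc <- .im(acc, ab)
            .ieq(acc, .im(.iv("a", n), .iv("b", n)),
                 label = sprintf("(ab)^%d = a^%d b^%d", n, n, n))
          }),
          multilinear = FALSE,
          description = "(ab)^n = a^n b^n"),
    .idef("power_commute", c("x", "y"),
          pow_cases(function(n, m) .ieq(.im(.iv("x", n), .iv("y", m)),
                                        .im(.iv("y", m), .iv("x", n))),
                    list(c(1, 2), c(2, 2), c(2, 3))),
          multilinear = FALSE,
          description = "x^n y^m = y^m x^n  (m >= 2)"),
    .idef("power_sandwich", c("x", "y"),
          pow_cases(function(n, m) .ieq(
            .im(.im(.iv("x", n), .iv("x", m)), .iv("y")),
            .im(.iv("y"), .im(.iv("x", m), .iv("x", n)))),
            list(c(1, 2), c(2, 2), c(1, 3))),
          multilinear = FALSE,
          description = "(x^n x^m)y = y(x^m x^n)  (m >= 2)"),
    .idef("gen_jordan_mn", c("x", "y"),
          pow_cases(function(m, n) .ieq(
            .im(.im(.iv("x", m), .iv("y")), .iv("x", n)),
            .im(.iv("x", m), .im(.iv("y"), .iv("x", n)))),
            list(c(1, 2), c(2, 2), c(2, 3))),
          multilinear = FALSE,
          description = "(x^m y)x^n = x^m(y x^n)  (n >= 2)")
  )
  names(defs) <- vapply(defs, function(d) d$name, character(1))
  defs
}

# identities derived in the paper-level theory only under the hypothesis
# "left almost + both alternative laws"; classify() gates on that
.conditional_suite <- c("square_commute", "square_left_assoc", "square_assoc",
                        "square_exchange", "medial_exchange", "power_sum",
                        "power_power", "product_power", "power_commute",
                        "power_sandwich", "gen_jordan_mn")

.get_identity <- function(id) {
  if (inherits(id, "laa_identity")) return(id)
  cat_ <- identity_catalog()
  if (!id %in% names(cat_))
    stop("unknown identity '", id, "'; available: ",
         paste(names(cat_), collapse = ", "), call. = FALSE)
  cat_[[id]]
}

## ---- random exact elements ----

#' Draw a random exact element of an algebra
#'
#' Coefficients are exact fractions with a common denominator at most
#' `denominator_bound` (for ordered fields) or uniform field elements (for
#' finite fields).  With `weight1 = TRUE` the last coordinate is set to
#' complete the coefficient sum to exactly 1.  Uses the current RNG state;
#' seed with `set.seed()` or let callers pass a seed.
#'
#' @param A A `laa_algebra`.
#' @param weight1 Force coefficient sum 1?
#' @param denominator_bound Bound on the common denominator.
#' @return A `laa_element`.
#' @export
random_element <- function(A, weight1 = TRUE, denominator_bound = 12) {
  f <- A$field
  n <- A$n
  if (f$kind == "finite") {
    els <- field_elements(f)
    cf <- lapply(seq_len(n), function(i) els[[sample.int(length(els), 1)]])
    if (weight1) {
      s <- sc_zero(f)
      for (i in seq_len(n - 1)) s <- sc_add(s, cf[[i]])
      cf[[n]] <- sc_sub(sc_one(f), s)
    }
    return(structure(list(f = f, coeffs = cf), class = "laa_element"))
  }
  q <- sample(2:max(2, denominator_bound), 1)
  nums <- sample(seq(-q, q), n, replace = TRUE)
  cf <- lapply(seq_len(n), function(i) sc_rat(f, nums[i], q))
  if (f$kind == "quadratic") {
    # include a surd part; for weight-1 the surd parts must cancel
    bn <- sample(seq(-q, q), n, replace = TRUE)
    if (weight1) bn[n] <- -sum(bn[-n])
    cf <- lapply(seq_len(n), function(i) {
      sc_add(cf[[i]], sc_mul(.sc(f, c(0, 1), c(1, 1)), sc_rat(f, bn[i], q)))
    })
  }
  if (weight1) {
    s <- sc_zero(f)
    for (i in seq_len(n - 1)) s <- sc_add(s, cf[[i]])
    cf[[n]] <- sc_sub(sc_one(f), s)
  }
  structure(list(f = f, coeffs = cf), class = "laa_element")
}

## ---- checking ----

.report <- function(name, mode, verdict, counterexample = NULL,
                    sample_size = NULL, seed = NULL) {
  structure(list(name = name, mode = mode, verdict = verdict,
                 counterexample = counterexample,
                 sample_size = sample_size, seed = seed),
            class = "laa_identity_report")
}

#' @export
print.laa_identity_report <- function(x, ...) {
  cat(sprintf("identity '%s': %s  [mode: %s%s]\n", x$name, x$verdict, x$mode,
              if (!is.null(x$sample_size))
                sprintf(", %d samples, seed %s", x$sample_size, x$seed) else ""))
  if (!is.null(x$counterexample)) {
    w <- x$counterexample
    cat("  counterexample (", w$equation, "):\n", sep = "")
    for (v in names(w$assignment))
      cat("    ", v, " = ", w$assignment[[v]], "\n", sep = "")
    cat("    lhs = ", w$lhs, "\n    rhs = ", w$rhs, "\n", sep = "")
  }
  invisible(x)
}

# evaluate every equation of an identity under an assignment; returns NULL
# if all hold, else the witness description
.check_assignment <- function(A, id, env, describe) {
  for (eq in id$equations) {
    lhs <- .tree_eval(A, eq$lhs, env)
    rhs <- .tree_eval(A, eq$rhs, env)
    if (!el_eq(lhs, rhs)) {
      return(list(assignment = describe(env), equation = eq$label,
                  lhs = format(lhs), rhs = format(rhs)))
    }
  }
  NULL
}

# iterate over all tuples idx in {1..m}^arity, calling fn(idx); fn returns
# non-NULL to short-circuit
.tuple_scan <- function(m, arity, fn) {
  idx <- rep(1L, arity)
  repeat {
    r <- fn(idx)
    if (!is.null(r)) return(r)
    pos <- arity
    while (pos >= 1L) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= m) break
      idx[pos] <- 1L
      pos <- pos - 1L
    }
    if (pos < 1L) return(NULL)
  }
}

#' Check one identity on an algebra
#'
#' Three modes are available.  `"basis"` evaluates the identity on every
#' tuple of basis elements; by bilinearity this proves a *multilinear*
#' identity for all elements, and the mode is refused for non-multilinear
#' identities (where basis checking is unsound: a variable occurring twice
#' couples cross terms that basis tuples never exercise).  `"sample"` tests
#' exact random elements — weight-1 by default for identities whose
#' derivation assumes idempotent populations — and can only return
#' `holds-on-sample`.  `"exhaustive"` enumerates all coefficient vectors
#' over a finite field.  `"auto"` picks basis for multilinear identities,
#' exhaustive for small finite-field problems, and sampling otherwise.
#'
#' @param A A `laa_algebra`.
#' @param id An identity name from [identity_catalog()] or a definition.
#' @param mode `"auto"`, `"basis"`, `"sample"`, or `"exhaustive"`.
#' @param sample_size Number of random assignments in sample mode.
#' @param seed RNG seed for sample mode (recorded in the report).
#' @param weight1 Restrict sampled/enumerated elements to weight 1; default
#'   (`NULL`) uses the identity's own flag, or `TRUE` for non-multilinear
#'   identities on star algebras, whose theory assumes weight-1 elements.
#' @return A `laa_identity_report`; a failing verdict always carries a
#'   counterexample that re-evaluates to unequal sides.
#' @export
#' @examples
#' M3 <- star_algebra(3)
#' check_identity(M3, "left_invertive", mode = "basis")
#' check_identity(M3, "associative", mode = "basis")
check_identity <- function(A, id, mode = c("auto", "basis", "sample", "exhaustive"),
                           sample_size = 100, seed = 1, weight1 = NULL) {
  id <- .get_identity(id)
  mode <- match.arg(mode)
  if (is.null(weight1)) {
    weight1 <- id$weight1_only ||
      (!id$multilinear && identical(A$provenance$constructor, "star_algebra"))
  }
  if (mode == "auto") {
    mode <- if (id$multilinear) "basis"
    else if (A$field$kind == "finite" &&
             .field_card(A$field)^(A$n * min(id$arity, 2)) <= 65536 &&
             id$arity <= 3) "exhaustive"
    else "sample"
  }
  if (mode == "basis") {
    if (!id$multilinear)
      stop("basis-exhaustive checking is unsound for '", id$name,
           "': the identity is not multilinear (a variable occurs more than ",
           "once per side), so holding on basis tuples does not imply it ",
           "holds for all elements; use mode = \"sample\" or \"exhaustive\"",
           call. = FALSE)
    basis <- lapply(seq_len(A$n), function(i) basis_element(A, i))
    witness <- .tuple_scan(A$n, id$arity, function(idx) {
      env <- stats::setNames(basis[idx], id$vars)
      .check_assignment(A, id, env, function(e)
        stats::setNames(as.list(A$basis[idx]), id$vars))
    })
    return(.report(id$name, "basis-exhaustive",
                   if (is.null(witness)) "holds" else "fails", witness))
  }
  if (mode == "exhaustive") {
    if (A$field$kind != "finite")
      stop("element-exhaustive checking requires a finite field", call. = FALSE)
    els <- field_elements(A$field)
    # all coefficient vectors, optionally restricted to weight 1
    vecs <- list()
    .tuple_scan(length(els), A$n, function(idx) {
      cf <- els[idx]
      if (weight1) {
        s <- sc_zero(A$field)
        for (c in cf) s <- sc_add(s, c)
        if (!sc_is_one(s)) return(NULL)
      }
      vecs[[length(vecs) + 1L]] <<- structure(
        list(f = A$field, coeffs = cf), class = "laa_element")
      NULL
    })
    if (length(vecs)^id$arity > 2e5)
      stop("element-exhaustive check too large (", length(vecs), "^",
           id$arity, " tuples); use mode = \"sample\"", call. = FALSE)
    witness <- .tuple_scan(length(vecs), id$arity, function(idx) {
      env <- stats::setNames(vecs[idx], id$vars)
      .check_assignment(A, id, env, function(e)
        lapply(e, format))
    })
    return(.report(id$name, "element-exhaustive",
                   if (is.null(witness)) "holds" else "fails", witness))
  }
  # sample mode
  witness <- .with_seed(seed, {
    w <- NULL
    for (rep in seq_len(sample_size)) {
      env <- stats::setNames(
        lapply(seq_len(id$arity), function(i) random_element(A, weight1 = weight1)),
        id$vars)
      w <- .check_assignment(A, id, env, function(e) lapply(e, format))
      if (!is.null(w)) break
    }
    w
  })
  .report(id$name, if (weight1) "weight1-sample" else "sample",
          if (is.null(witness)) "holds-on-sample" else "fails",
          witness, sample_size = sample_size, seed = seed)
}

#' Find a left identity element, if one exists
#'
#' Solves the exact linear system `e a_j = a_j` for all basis elements
#' `a_j`.  Returns the solution element, or `NULL` when the system is
#' inconsistent (most gametic and star algebras have no left identity).
#'
#' @param A A `laa_algebra`.
#' @return A `laa_element`, or `NULL`.
#' @export
find_left_identity <- function(A) {
  n <- A$n
  f <- A$field
  # unknowns e_1..e_n; equations: sum_i e_i gamma[i,j,k] = delta_jk
  M <- vector("list", n * n * n); dim(M) <- c(n * n, n)
  b <- vector("list", n * n)
  row <- 0L
  for (j in seq_len(n)) for (k in seq_len(n)) {
    row <- row + 1L
    for (i in seq_len(n)) M[[row, i]] <- A$tensor$gamma[[i, j, k]]
    b[[row]] <- if (j == k) sc_one(f) else sc_zero(f)
  }
  sol <- .lin_solve(f, M, b)
  if (sol$status == "inconsistent") return(NULL)
  e <- structure(list(f = f, coeffs = sol$x), class = "laa_element")
  # defensive: verify (free variables were zeroed for underdetermined systems)
  for (j in seq_len(n)) {
    if (!el_eq(multiply(A, e, basis_element(A, j)), basis_element(A, j)))
      return(NULL)
  }
  e
}

#' Classify an algebra against the identity catalog
#'
#' Runs every catalog identity with the soundest applicable mode:
#' basis-exhaustive for multilinear identities, element enumeration over
#' small finite fields, exact weight-1 sampling otherwise.  The derived
#' consequences (square exchange rules, power laws, the generalized Jordan
#' family) are only meaningful under the hypothesis that the algebra is
#' left almost *and* alternative; when that gate fails they are reported as
#' `"not-applicable"` rather than asserted.
#'
#' @param A A `laa_algebra`.
#' @param sample_size,seed Passed to [check_identity()] for sampled checks.
#' @return A list with `verdicts` (named character vector) and `reports`
#'   (the full report objects).
#' @export
#' @examples
#' cl <- classify(mendelian_gametic(2))
#' cl$verdicts[c("commutative", "associative")]
classify <- function(A, sample_size = 100, seed = 1) {
  cat_ <- identity_catalog()
  reports <- list()
  verdicts <- character(0)
  core <- setdiff(names(cat_), .conditional_suite)
  for (nm in core) {
    rep_ <- check_identity(A, cat_[[nm]], mode = "auto",
                           sample_size = sample_size, seed = seed)
    reports[[nm]] <- rep_
    verdicts[nm] <- rep_$verdict
  }
  gate <- all(verdicts[c("left_invertive", "alternative_left",
                         "alternative_right")] %in%
              c("holds", "holds-on-sample"))
  for (nm in .conditional_suite) {
    if (!gate) {
      verdicts[nm] <- "not-applicable"
      next
    }
    rep_ <- check_identity(A, cat_[[nm]], mode = "auto",
                           sample_size = sample_size, seed = seed)
    reports[[nm]] <- rep_
    verdicts[nm] <- rep_$verdict
  }
  list(verdicts = verdicts, reports = reports, gate_passed = gate)
}
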