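# Fixtures built in code: small fields and algebras used across the suite.

gf4 <- function() make_finite_field(2, 2, c(1, 1, 1))

gf4_t <- function() scalar(gf4(), c(0, 1))

# commutative associative fixture: a_i a_j = delta_ij a_i (diagonal tensor);
# every catalog identity holds here, and (1, ..., 1) is a two-sided identity
diagonal_algebra <- function(field, n = 2) {
  ent <- array("0", dim = c(n, n, n))
  for (i in seq_len(n)) ent[i, i, i] <- "1"
  algebra(field, paste0("a", seq_len(n)), structure_tensor(field, ent),
          provenance = list(constructor = "diagonal_fixture"))
}

# star algebra over GF(4) with alpha = t
star_gf4 <- function(n) star_algebra(n, gf4(), gf4_t())

expect_scalar_equal <- function(x, y) {
  expect_true(x == y, label = sprintf("%s == %s", format(x), format(y)))
}

expect_element_equal <- function(x, y) {
  expect_true(x == y, label = sprintf("%s == %s", format(x), format(y)))
}

# exact equality of two algebras' tensors
tensors_equal <- function(A, B) {
  if (A$n != B$n) return(FALSE)
  for (i in seq_len(A$n)) for (j in seq_len(A$n)) for (k in seq_len(A$n))
    if (!isTRUE(A$tensor$gamma[[i, j, k]] == B$tensor$gamma[[i, j, k]]))
      return(FALSE)
  TRUE
}

zero_element <- function(A) element(A, rep(0, dim(A)))
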