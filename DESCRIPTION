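Package: laalgebra
Title: Exact Nonassociative Algebras of Genetic Inheritance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct and analyse the finite-dimensional nonassociative
    algebras that arise in mathematical genetics: gametic and zygotic
    algebras, Gonshor's two-allele mutation algebra, and the noncommutative
    left almost (star) algebras built from a scalar satisfying
    alpha + alpha^2 = 1. All computation is carried out in exact
    arithmetic over the rationals, a real quadratic extension such as
    Q(sqrt(5)), or a finite field such as GF(4). The package verifies
    multilinear identities exhaustively on basis tuples, tests
    non-multilinear identities on exact weight-1 samples or by element
    enumeration over finite fields, classifies algebras against a catalog
    of identities (left invertive, flexible, alternative, Jordan and their
    derived consequences), finds idempotent elements as population
    equilibria (Hardy-Weinberg and mutation equilibria), and iterates the
    random-mating squaring map. Algebras are exchanged through a JSON
    format with exact scalar strings, and a command-line interface wraps
    the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
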