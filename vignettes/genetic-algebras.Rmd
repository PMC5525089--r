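---
title: "Exact nonassociative algebras of genetic inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact nonassociative algebras of genetic inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laalgebra)
```

## The model

A one-locus inheritance system with gametes $a_1, \dots, a_n$ is encoded
as a finite-dimensional algebra: the bilinear product

$$a_i a_j = \sum_{k=1}^{n} \gamma_{ijk} a_k$$

lists the offspring gamete distribution of the cross $a_i \times a_j$.
The *gametic* constraints are that each row $(\gamma_{ij1}, \dots,
\gamma_{ijn})$ is a probability vector (row sums 1, entries in $[0,1]$ on
ordered fields) and, classically, that mating is commutative,
$\gamma_{ijk} = \gamma_{jik}$.  The *left almost* (LA) variant keeps the
stochastic constraints but drops the symmetry, admitting noncommutative
gametic algebras; its flagship example is the star algebra
$a_i \star a_j = \alpha a_i + \alpha^2 a_j$ with $\alpha + \alpha^2 = 1$,
which satisfies the left invertive law $(xy)z = (zy)x$.

The coefficient sum $\omega(x) = \sum_i \lambda_i$ is the baric weight:
for any row-stochastic tensor it is an algebra homomorphism,
$\omega(xy) = \omega(x)\omega(y)$, and the biologically meaningful states
are the weight-1 elements (populations; coordinates are gene
frequencies).  Random mating of a population with itself is the squaring
map $x \mapsto x^2$, and idempotents $x^2 = x$ are its equilibria:
Hardy–Weinberg states in zygotic algebras, the point
$\left(\frac{s}{r+s}, \frac{r}{r+s}\right)$ in the two-allele mutation
algebra with rates $r, s$.

Three scalar domains cover every construction the package supports:
exact rationals, the real quadratic extension $\mathbb{Q}(\sqrt d)$
(default $d = 5$, home of the roots $(-1 \pm \sqrt 5)/2$ of
$x^2 + x = 1$), and finite fields $GF(p^k)$ (canonically $GF(4)$ built
from $t^2 + t + 1$, where $\alpha = t$ also satisfies
$\alpha + \alpha^2 = 1$).  All arithmetic is exact: fractions are kept
reduced with positive denominators, quadratic scalars as pairs of
fractions, finite-field elements as coefficient vectors reduced modulo
the modulus.  Canonical forms make equality a representation comparison,
so every verdict the package emits is decidable, and every reported
counterexample re-evaluates to genuinely unequal elements.

## Why identity checking is organised around multilinearity

An identity like commutativity, associativity or the left invertive law
is *multilinear*: each variable occurs exactly once on each side.  For
such identities, both sides are multilinear maps, so agreement on all
tuples of basis elements proves the identity for all elements — the
`basis` mode of `check_identity()` is an exhaustive proof with $n^a$
evaluations ($a$ = arity).  A non-multilinear identity such as the
flexible law $(xy)x = x(yx)$ cannot be decided this way (basis tuples
never exercise the cross terms of a repeated variable), and the checker
refuses the unsound mode rather than silently producing a wrong answer.
Non-multilinear identities are decided by full element enumeration over
small finite fields, or tested on exact random samples otherwise; a
sampled verdict is reported as `holds-on-sample`, never as `holds`.

Sampling defaults to weight-1 elements for non-multilinear checks on
star algebras.  The reason is mathematical, not cosmetic: in a star
algebra $X \star X = \omega(X) X$, so $X^2 = X$ holds precisely on
weight-1 elements, and the flexible/generalized-Jordan properties of
these algebras are statements about populations.  On weight-1 samples
both hold; the checker confirms this rather than assuming it.

The derived consequences in the catalog — $x^2 y = y x^2$, the square
exchange rules, the four-variable medial exchange, the power laws
$a^m a^n = a^{m+n}$, $(a^m)^n = a^{mn}$, $(ab)^n = a^n b^n$, and the
generalized Jordan family $(x^m y) x^n = x^m (y x^n)$ — are theorems
*conditional* on the algebra being left almost **and** alternative.
`classify()` therefore gates them: when either hypothesis fails (star
algebras fail both alternative laws), the suite is reported as
`not-applicable` instead of being asserted vacuously or misleadingly.
The gate matters because no nontrivial algebra in the package satisfies
both hypotheses; the suite is exercised for real on
commutative-associative fixtures (e.g. the diagonal tensor algebra over
$GF(4)$), where all of it holds element-exhaustively.  Power identities
are checked at the exponent instances $(m, n) \in \{(1,2), (2,2),
(2,3)\}$ (and analogues): powers are *principal* (left-normed,
$a^{n+1} = a^n a$), the only power convention a nonassociative algebra
fixes without further axioms.

## Constructors and two deliberate completions

`mendelian_gametic(n)` builds $\gamma_{ijk} = \frac{1}{2}(\delta_{ik} +
\delta_{jk})$; `gametic_from_tensor()` validates arbitrary tensors
(reporting every violated constraint with its indices);
`random_gametic()` draws seeded random row-stochastic tensors with exact
entries $c_k / q$ via multinomial compositions — the fixture source for
property tests; `star_algebra()` and `mutation_algebra()` cover the
noncommutative and mutation cases; `zygotic_duplicate()` performs
commutative duplication.

Two places required a decision the definitions leave open:

* **The $R^2$ row of the mutation algebra.**  The classical presentation
  specifies $D^2 = (1-r) D + r R$ and $DR = \frac{1-r+s}{2} D +
  \frac{1-s+r}{2} R$, together with the assertion that in the basis
  $a = D$, $b = D - R$ the products become $a^2 = a - rb$,
  $ab = \frac{1-r-s}{2} b$, $b^2 = 0$.  The $R^2$ row is not printed,
  but it is forced: writing $R^2 = uD + vR$ and expanding
  $b^2 = D^2 - 2DR + R^2$ coordinatewise, $b^2 = 0$ requires exactly
  $u = s$, $v = 1 - s$.  So we complete $R^2 = sD + (1-s)R$ — the mirror
  image of the $D^2$ row with the alleles and the rates swapped — and
  the test suite verifies the whole basis change symbolically in
  $(r, s)$ (on a grid of exact rates, which suffices because every
  entry is a polynomial of degree $\le 1$ in each rate).

* **The duplication coefficients.**  Zygotic multiplication is specified
  only as "random mating of $e_{ij}$ with $e_{pq}$ produces $e_{ks}$ in
  some ratio".  We use the classical commutative-duplication rule: the
  offspring genotype distribution is the symmetrised product of the two
  parents' gamete distributions,
  $\gamma_{ij,pq,(k,s)} = \gamma_{ijk}\gamma_{pqs} +
  \gamma_{ijs}\gamma_{pqk}$ for $k < s$ and $\gamma_{ijk}\gamma_{pqk}$
  on the diagonal.  This is the unique choice under which drawing one
  gamete from each parent independently gives the genotype frequencies,
  and it reproduces the 1:2:1 heterozygote cross and the Hardy–Weinberg
  idempotents.

Zygote basis order is lexicographic in $(i, j)$ with $i \le j$; all
public indices are 1-based.

Constructors that need $\tfrac12$ (Mendelian, mutation) reject fields of
characteristic 2 explicitly: $1/2$ does not exist there, and the
characteristic-2 star algebra over $GF(4)$ never mixes with them.  Both
field choices for $\alpha$ — the quadratic roots and $t \in GF(4)$ — are
supported on equal footing, since the theory is agnostic between them.

## Equilibrium finding

`find_idempotents()` works in three regimes.

1. **Finite fields**: exhaustive enumeration of all coefficient vectors
   (bounded at $10^5$), optionally restricted to weight 1.  For the
   4-generator star algebra over $GF(4)$ this confirms that the
   idempotents are exactly the $4^3 = 64$ weight-1 vectors (and 0).
2. **Ordered fields, symbolic**: the residual $x^2 - x$ restricted to
   the weight-1 affine space is a quadratic polynomial in the $m = n-1$
   free coordinates.  It is first evaluated on the grid $\{0,1,2\}^m$:
   a polynomial of degree $\le 2$ in each variable vanishing there is
   identically zero, so a fully idempotent weight-1 set (Mendelian,
   star) is recognised *exactly*, in any dimension, without solving
   anything.  Otherwise the coefficients are recovered by exact
   interpolation and the system is solved: directly for $m = 1$
   (quadratic formula, with square roots sought inside the field — a
   rational discriminant may resolve in $\mathbb{Q}(\sqrt d)$), by
   Sylvester-resultant elimination for $m = 2$.  An identically
   vanishing resultant signals a positive-dimensional solution variety;
   it is reported as a continuum with its defining polynomial
   constraints and a few exact sample points found by scanning rational
   lines (for the zygotic 2-allele algebra this recovers the
   Hardy–Weinberg curve, with constraint equivalent to
   $x_2^2 = 4 x_1 x_3$).  Root search beyond degree 2 uses the
   rational-root theorem with deflation; isolated equilibria whose
   coordinates are quadratic irrationals outside $\mathbb{Q}(\sqrt d)$,
   or of higher algebraic degree, are outside the symbolic method's
   reach — a documented limitation rather than a silent wrong answer,
   since every candidate is verified by exact substitution before being
   returned.
3. **Grid method** (`method = "grid"`): iterates the squaring map in
   floating point from each grid start (so attracting equilibria are
   reached), rationalises the numeric limit by continued fractions
   (denominators up to 512), and keeps only points that verify
   $x^2 = x$ exactly.  It can only find equilibria with such rational
   coordinates, and only attracting or grid-adjacent ones; it is the
   fallback for dimensions the symbolic method declines.

`evolve()` keeps all iterates exact.  A practical consequence of
exactness: coefficients' denominators can square with each generation,
so long exact trajectories eventually exceed the 2^52 integer guard and
fail loudly rather than round silently.  The geometric contraction law
$u_{g+1} - u^\ast = (1-r-s)(u_g - u^\ast)$, which the tests verify
exactly over 6–16 generations, is the honest statement of convergence;
numeric summaries (`as.data.frame()` on a trajectory) are available for
plotting.  The convergence *flag* uses a max-norm tolerance (default
$10^{-9}$) on ordered fields and affects nothing but itself.
`distance_to_set()` is exact: max-norm to the nearest returned point,
or $|\omega(x) - 1| / n$ to the full weight-1 continuum; for polynomial
continua it falls back to the stored sample points (an upper bound).

## What the random fixtures do and do not show

`random_gametic()` emulates arbitrary one-locus inheritance tables:
row-stochastic tensors with exact entries, symmetric (classical) or not
(LA variant), with denominators bounded by `denominator_bound`
(default 8 — coarse gamete distributions, deliberately small to keep
products well inside the exact-integer range).  Random weight-1 elements
use a common denominator up to 12, with surd parts cancelling so the
weight is exactly 1 in quadratic fields.  What passing these tests shows
is that the algebraic machinery (bilinearity, weight homomorphism,
validation, duplication, serialisation) is correct on the whole
constraint class, not just on textbook examples.  What it does not show:
anything about multi-locus systems, selection, sex linkage, or
non-stochastic tensors — none of which are modelled here; and sampled
identity verdicts remain sample verdicts.

## Problem sizes and determinism

The shipped tests prove multilinear identities basis-exhaustively for
star algebras of dimension 2–6 over both $\mathbb{Q}(\sqrt5)$ and
$GF(4)$, enumerate $GF(4)$-algebras up to $4^4$ elements, sample
non-multilinear identities at 50–200 exact draws, and follow mutation
trajectories for 6–16 generations — sizes chosen so that every
intermediate integer stays far below the exactness guard while still
covering each code path.  Every randomised step takes an explicit seed
(constructor provenance records it; CLI outputs embed it), so all
artifacts are bit-for-bit reproducible.
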