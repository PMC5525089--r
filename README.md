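# laalgebra

Exact-arithmetic construction and analysis of the nonassociative algebras
that arise in mathematical genetics.

## The problem

When a one-locus trait with alleles $a_1,\dots,a_n$ is followed through
random mating, the natural bookkeeping device is a *gametic algebra*: an
$n$-dimensional algebra whose product

$$a_i a_j = \sum_{k=1}^n \gamma_{ijk}\, a_k,
\qquad \sum_k \gamma_{ijk} = 1,\quad 0 \le \gamma_{ijk} \le 1$$

records the offspring gamete distribution of a cross, with the structure
constants $\gamma_{ijk}$ read as relative gene frequencies.  A population
is a weight-1 element $x = \sum \lambda_i a_i$, $\sum \lambda_i = 1$, and
one round of random mating maps $x \mapsto x^2$.  These algebras are
commutative but *not* associative, and the classical families — Mendelian
gametic, zygotic (genotype) algebras obtained by commutative duplication,
and Gonshor's two-allele mutation algebra with rates $r$ (D→R) and $s$
(R→D) — sit alongside a noncommutative relative: the *left almost* (LA)
star algebra

$$a_i \star a_j = \alpha a_i + \alpha^2 a_j, \qquad \alpha + \alpha^2 = 1,$$

which satisfies the left invertive law $(xy)z = (zy)x$ instead of
commutativity.  Valid scalars $\alpha$ are the exact roots
$(-1 \pm \sqrt 5)/2$ in $\mathbb{Q}(\sqrt 5)$, or the generator $t$ of
$GF(4)$ (where $t^3 = 1$ and $t + t^2 = 1$).

Whether such an algebra is flexible, alternative, Jordan, or power
associative is a statement about polynomial identities, and floating
point is useless for deciding them.  `laalgebra` therefore computes
*exactly* — over the rationals, over real quadratic extensions such as
$\mathbb{Q}(\sqrt 5)$, and over finite fields such as $GF(4)$ — and
decides identities soundly: multilinear identities by exhaustive basis
evaluation (a proof, by bilinearity), non-multilinear ones by element
enumeration over finite fields or on exact random weight-1 samples.
Idempotents $x^2 = x$ are found as the population equilibria
(Hardy–Weinberg states, mutation equilibria) they represent.

Intended users: researchers in algebraic genetics and nonassociative
algebra who want machine-checked instances of structural claims, and
teaching contexts where Hardy–Weinberg / mutation equilibria are derived
algebraically.

## Worked example

```r
library(laalgebra)

# the 3-generator star algebra over Q(sqrt(5)), alpha = (-1+sqrt(5))/2
M3 <- star_algebra(3)
check_identity(M3, "left_invertive", mode = "basis")
#> identity 'left_invertive': holds  [mode: basis-exhaustive]
check_identity(M3, "commutative", mode = "basis")
#> identity 'commutative': fails  [mode: basis-exhaustive]
#>   counterexample ((x y) = (y x)):
#>     x = a1
#>     y = a2
#>     lhs = (-1/2 + 1/2*sqrt(5), 3/2 - 1/2*sqrt(5), 0)
#>     rhs = (3/2 - 1/2*sqrt(5), -1/2 + 1/2*sqrt(5), 0)
```

The basis-exhaustive check is a proof: both identities are multilinear,
so their truth on all basis triples decides them for every element.  The
counterexample shows $a_1 a_2 = \alpha a_1 + \alpha^2 a_2$ against
$a_2 a_1 = \alpha^2 a_1 + \alpha a_2$ with $\alpha = (-1+\sqrt5)/2$,
exactly.

```r
# mutation with rates r = 1/4 (D to R) and s = 1/2 (R to D)
Mu <- mutation_algebra("1/4", "1/2")
find_idempotents(Mu)
#> <equilibria> kind: isolated (1 point, method symbolic, weight-1)
#>    (2/3, 1/3)
as.data.frame(evolve(Mu, basis_element(Mu, 1), generations = 8))
#>   generation         D         R
#> 1          0 1.0000000 0.0000000
#> 2          1 0.7500000 0.2500000
#> 3          2 0.6875000 0.3125000
#> ...
#> 9          8 0.6666718 0.3333282
```

The unique weight-1 idempotent $(2/3, 1/3)$ is the mutation equilibrium
$(s/(r+s),\, r/(r+s))$; a population starting from pure $D$ approaches it
geometrically with exact ratio $1 - r - s = 1/4$ per generation.

```r
# zygotic algebra of the 2-allele Mendelian gametic algebra
Z <- zygotic_duplicate(mendelian_gametic(2))
h <- basis_element(Z$algebra, 2)        # the heterozygote e12
multiply(Z$algebra, h, h)
#> (1/4, 1/2, 1/4)
```

— the 1:2:1 Mendelian ratio of a heterozygote cross, and the weight-1
idempotents of `Z$algebra` are exactly the Hardy–Weinberg states
$(p^2, 2pq, q^2)$.

## Command line

A thin wrapper script is installed under `inst/cli/laalg`:

```sh
laalg make star --n 3 --field qsqrt5 --out m3.json
laalg check --in m3.json --identity left_invertive --mode basis --expect holds
laalg make mutation --r 1/4 --s 1/2 --out mu.json
laalg idempotents --in mu.json --weight1
laalg evolve --in mu.json --x0 "1,0" --gens 30 --out traj.csv
```

Algebras travel as a JSON exchange format whose scalars are exact strings
(`"1/4"`, never `0.25`); identity reports and equilibria are emitted as
JSON, trajectories as CSV.  Exit codes: 0 (completed), 1 (validation
failure), 2 (usage error).

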