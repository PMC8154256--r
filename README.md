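# kdentropy

Differential entropies of one-dimensional observables — in particular
backbone-dihedral conformational entropies from molecular-dynamics
trajectories — estimated with a binned Gaussian kernel density estimator
whose bandwidth is selected automatically by a diffusion-based plug-in
(improved Sheather–Jones) method.

## What it computes

For an observable $x$ with probability density $p(x)$, the entropy is

$$S = -R \int p(x)\,\ln p(x)\,\mathrm{d}x,$$

with $R$ the gas constant, so $S$ is in J/(mol K). The density is
estimated by a Gaussian KDE,

$$\hat p(x) = \frac{1}{N}\sum_{i=1}^{N}
\frac{1}{\sqrt{2\pi t}}\exp\!\left(-\frac{(x - X_i)^2}{2t}\right),$$

where $t$ is the squared kernel bandwidth. The data are first binned onto
a power-of-two grid (the *resolution* $r$); the convolution is then a
single attenuation $a_k \mapsto a_k e^{-k^2\pi^2 t/2}$ of the discrete
cosine transform of the bin frequencies, and $t$ is the root of the
plug-in fixed-point equation solved in the same transform domain. This
makes bandwidth selection and density evaluation fast and fully
automatic: no rule-of-thumb bandwidth and no hand-chosen bin width.

Dihedral angles get a dedicated periodic pipeline: samples are wrapped
into $[-180°, 180°)$, replicated into the neighboring periods, smoothed
on the triple window, and the central period is renormalized; the entropy
integral is taken with the angle in radians. Per-residue entropies
(e.g. $S_\phi + S_\psi$) quantify local, alignment-free flexibility and
can be written onto the B-factor column of a PDB file for structure-based
visualization. Accelerated-MD data are reweighted by 10th-order
Maclaurin weights $\sum_{k\le 10} (\beta\,\Delta V_i)^k / k!$ computed
from per-frame boost potentials.

## Worked example

```r
library(kdentropy)

set.seed(42)
x <- rnorm(20000, sd = 2)
est <- kde_entropy(x, label = "gaussian demo")
est
#> <entropy_estimate> gaussian demo: S = 17.7012 J/(mol K) (simpson rule, r = 64, h = 0.2882)
glance(est)
#> # A tibble: 1 × 6
#>   entropy integration_rule resolution bandwidth bw_converged n_samples
#>     <dbl> <chr>                 <int>     <dbl> <lgl>            <int>
#> 1    17.7 simpson                  64     0.288 TRUE             20000
analytic_gaussian_entropy(2)
#> [1] 17.56086
```

The estimate (17.70) sits within 0.8% of the closed form (17.56); the
one-row `glance()` reports the automatically selected resolution (64 bins
for 2·10⁴ points) and kernel bandwidth (0.288 data units, converged
fixed point).

Reweighting a biased (accelerated-MD-style) dihedral ensemble:

```r
fx <- generate_boosted_dihedral(50000, seed = 7)   # known truth: 8.8237 J/(mol K)
w  <- maclaurin_weights(fx$delta_v, temperature = fx$temperature)
dihedral_entropy(fx$angles)$value               # biased:     5.3368
dihedral_entropy(fx$angles, weights = w)$value  # reweighted: 9.0163
```

The raw biased ensemble underestimates the entropy by ~40%; the
Maclaurin-reweighted estimate recovers the analytic truth to ~2%.

Residuewise analysis from a cpptraj-style table:

```r
tbl <- read_dihedral_table("dihedrals.dat")       # '#Frame phi:1 psi:1 ...'
res <- residuewise_entropy(tbl)                   # tibble: one row per residue
project_to_bfactor(res, "structure.pdb", "entropy.pdb")
autoplot(res)
```

A thin command-line wrapper is installed as `exec/kdentropy` with `kde`,
`dihedral` and `fixtures` subcommands; diagnostics (resolution,
bandwidth, convergence) go to standard error, results to files or
standard output.

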