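# capsidhot

Conservation-based prediction of protein–protein interface **hot spots** in
icosahedral viral capsids, and the free-energy machinery used to validate
such predictions thermodynamically.

## The problem

An icosahedral capsid is built from 60 (or 60·T) chemically identical copies
of its capsid protein (CP). Self-assembly is driven by a small number of
interface residues whose mutation disproportionately weakens subunit
binding — the hot spots. `capsidhot` implements a purely structural,
conservation-based way to find them across a virus family, with no energy
function involved:

1. **Interface residues.** Assemble the full capsid from the icosahedral
   asymmetric unit using the 60-element rotation group *I*; a residue is an
   interface residue when one of its heavy atoms lies within a cutoff
   (default 4.5 Å) of a neighbouring subunit.
2. **Sequence conservation.** Columns of the family's multiple sequence
   alignment where all members carry the same residue, gap-free.
3. **Space conservation.** Project each interface residue onto the angular
   capsid map (φ = azimuth, ψ = colatitude of its position seen from the
   capsid center); a residue is conserved in quaternary position when the
   alignment-corresponding residue of every other member lies within a
   3° overlap threshold in both angles.

The **hot spots are the three-way intersection** of those sets, each
annotated with the symmetry fold (2-, 3-, 5-fold, or quasi) of the
interfaces it sits in.

The thermodynamic half of the package turns umbrella-sampling window series
(reaction coordinate: subunit center-of-mass separation ξ, harmonic biases
w(ξ) = ½k(ξ−ξᵢ)²) into an unbiased potential of mean force via the
**Weighted Histogram Analysis Method** (WHAM, solved in log space to a
10⁻⁸ kcal/mol gauge tolerance),

&nbsp;&nbsp;&nbsp;&nbsp;g(ξ) = −k_BT ln P(ξ), zero-referenced at large separation,

extracts the binding free energy ΔG as the global PMF minimum, and
differences variants against the wild type (ΔΔG = ΔG_mut − ΔG_wt) with block
bootstrap errors.

Everything is exercised end-to-end on seeded synthetic inputs: toy bead
capsid families with *planted* interface/conservation ground truth, and
umbrella samples drawn *exactly* (inverse CDF, no Markov-chain error) from
known 1D potentials.

## Worked example

```r
library(capsidhot)

# a seeded 4-member toy family (T=3: chains A, B, C) with planted truth
fam <- make_toy_family(toy_family_spec(seed = 7))
res <- run_prediction(fam$members)
res
#> Hot-spot prediction (reference toy01)
#>   interface residues (ref): 4
#>   sequence-conserved:       4
#>   space-conserved:          3
#>   hot spots:                9, 14
res$hot_spots
#>   resno   fold_class
#> 1     9 2-fold/quasi
#> 2    14 2-fold/quasi
```

Residues 9 and 14 are exactly `fam$truth$hot_spots`: the planted residues
that are simultaneously at a subunit interface, sequence-conserved across
the four members, and co-located on the capsid map within the 3° threshold.
Both sit at a 2-fold axis (they also touch the other chains of their own
asymmetric-unit copy, hence the additional `quasi` tag).

```r
# binding free energy from umbrella sampling over known potentials:
# wild type depth 5.0 kcal/mol, "mutant" depth 3.5 kcal/mol
wins <- make_umbrella_windows(0.8, 3.54, 42, spring_k = 2000)  # kJ/mol/nm^2
wt  <- sample_umbrella(potential_spec("morse", depth = 5.0), wins, 20000, seed = 1)
mut <- sample_umbrella(potential_spec("morse", depth = 3.5), wins, 20000, seed = 2)
run_pmf_analysis(list(WT = wt, E9Q = mut), wild_type = "WT")$table
#>   variant    dg dg_err  ddg ddg_err
#> 1      WT -4.88     NA 0.00      NA
#> 2     E9Q -3.42     NA 1.46      NA
```

The recovered ΔG values sit within bin resolution of the prescribed well
depths (−5.0 and −3.5 kcal/mol), and the mutation-induced ΔΔG of
1.46 kcal/mol matches the planted depth difference of 1.5.

A command-line interface wrapping the same functions ships at
`inst/cli/capsidhot.R` (subcommands `assemble`, `predict`, `wham`; one YAML
config drives all of them and every run writes its resolved config and seed
next to its outputs).

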