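# midiff

Functional differentiation in recurrent neural networks via adversarial
mutual-information minimization.

## The scientific problem

During development, neural populations specialize: distinct subgroups take
over distinct task functions, and modular activity appears before modular
anatomy.  `midiff` implements a computational account of this process: a
task-performing RNN (the *main model*, MM) whose recurrent layer is split
into two fixed halves, trained jointly with a feed-forward critic (the
*sub model*, SM) that estimates the mutual information (MI) between the
halves' states through the Donsker–Varadhan bound

    Î = E_joint[T_θ(h⁽¹⁾, h⁽²⁾)] − log E_shuffled[exp T_θ(h⁽¹⁾, h⁽²⁾)].

The SM performs gradient ascent on Î (tightening the bound, 20 iterations
per MM step after 100 pretraining iterations); the MM descends

    L = L_task + λ_reg · L_reg + λ_I · Î,

so the two halves are driven toward statistical independence while the
task is solved.  The package asks — and lets you measure — whether this
single information-theoretic constraint is enough to make the predefined
halves specialize, functionally and structurally.

Two benchmark settings are built in:

* **2-bit working memory** (leaky-integrator rate RNN): four pulse
  channels set two independent ±1 memory bits that must be held across
  thousands of steps;
* **chaotic signal separation** (GRU): the input is the sum of
  standardized Lorenz and Rössler trajectories, and two readout heads must
  reconstruct the components.

The analysis stack quantifies specialization against the predefined
partition: Newman modularity `Q_cor` (absolute activity correlations) and
`Q_str` (symmetrized absolute recurrent weights |W|+|Wᵀ|), separability
indices `D_out`, `D_in`, `D_cor` in [0, 1], task success (>90% correct
signs) and R², fast-greedy community detection with normalized-MI
agreement `I_n`.  All gradient machinery (BPTT through both architectures,
critic backprop, DV input gradients) is hand-written in RcppArmadillo and
finite-difference checked in the test suite.

## Worked example

One desk-scale working-memory trial (N = 32, batch 8, 800 MM cycles,
λ_I = 0.15; a few minutes on one CPU):

```r
library(midiff)
cfg <- midiff_profile("wm", "fast", eval_every = 100L, seed = 3)
tr  <- run_trial(cfg)
unlist(tr$final[c("correct_fraction", "L_task", "Q_cor", "Q_str",
                  "D_cor", "D_in", "D_out", "I_n")])
#> correct_fraction  L_task   Q_cor    Q_str    D_cor   D_in   D_out    I_n
#>            0.957   0.182   0.264   -0.005    0.631   0.16    0.17   0.72
```

Reading the numbers: the trial passes the strict success criterion (95.7%
of post-transient output signs correct, > 90%); the held-out task MSE is
0.18; functional modularity `Q_cor = 0.26` and correlation separability
`D_cor = 0.63` show that the two predefined halves each specialize on one
memory bit (a trial trained with `lambda_I = 0` stays near `Q_cor ≈ 0`,
`D_cor ≈ 0.07`); structural modularity `Q_str` is still near zero at this
short desk scale — weight reorganization develops much more slowly than
functional reorganization; and `I_n = 0.72` says the communities found by
fast-greedy detection on the correlation graph largely coincide with the
predefined halves.

Multi-trial condition sweeps (±MI, ±L2) run through
`experiment_spec()` / `run_experiment()`, time courses through
`timecourse_report()`; thin CLI wrappers live in `inst/scripts/`
(`train.R`, `experiment.R`) with YAML profiles in `inst/configs/`.

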